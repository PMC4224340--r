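Package: archevol
Title: Event-Grammar Parsimony Analysis of Multi-Domain Gene Architectures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the evolution of multi-domain gene
    architectures on a species tree, motivated by the folB-folK-folP gene
    fusion of the pterin branch of folate biosynthesis. Provides a formal
    event grammar over genome profiles (fusion, fission by separation,
    fission by domain loss, domain contraction, tandem domain duplication,
    gene loss and gene gain), a minimum-cost event distance between
    profiles, Sankoff-style weighted-parsimony reconstruction of ancestral
    profiles with enumeration of most-parsimonious reconstructions,
    validation and summarisation of stated per-branch event scenarios, a
    continuous-time Gillespie simulator of architecture evolution along
    branch lengths, and the folate pterin-branch case-study dataset as an
    executable fixture.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
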