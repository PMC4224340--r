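---
title: "Modelling fusion and fission of multi-domain gene architectures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fusion and fission of multi-domain gene architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archevol)
```

## The character and its state space

`archevol` treats one pathway's gene complement in one genome as a single
evolving character: a **genome profile**, the multiset of domain
architectures of the pathway's genes. An architecture is an ordered N→C
string of domain symbols from a registered alphabet; the default alphabet
`{B, K, P}` names the folB (DHNA), folK (HPPK) and folP (DHPS) domains of
the pterin branch of folate biosynthesis. `B-B;K-P` is a genome carrying a
tandem-folB two-domain gene plus a folK–folP fusion; `.` is a genome that
has lost the pathway.

Profiles are compared as multisets: genomic location and synteny are
evidence used when *coding* a tip state, not part of the character itself.
The state space is bounded by explicit caps (`arch_caps()`): at most 2
copies of a domain type within one gene — matching the observed folB–folB
tandem — and at most 4 genes per profile. The caps are a modelling
statement that larger amplifications are outside the questions this
machinery answers, and they keep every search finite.

## The event grammar

Seven transition types connect profiles:

| type | arity | meaning |
|---|---|---|
| `fusion` | 2→1 | concatenate two genes, N→C |
| `fission_separation` | 1→2 | split one gene at a domain boundary; all domains retained |
| `fission_domain_loss` | 1→1 | delete a contiguous run from a gene with ≥ 2 distinct domain types |
| `domain_contraction` | 1→1 | delete a run from a single-domain-type gene (e.g. `B-B` → `B`) |
| `domain_duplication` | 1→1 | insert a tandem copy of a contiguous run |
| `gene_loss` | 1→0 | remove a gene |
| `gene_gain` | 0→1 | a stated architecture appears (e.g. horizontal transfer) |

Three grammar decisions deserve comment. First, fusion generates **both**
concatenation orders: the case study only exhibits the `B-K-P` order, but
the grammar must not presuppose the order that selection happened to
preserve. Second, a deletion that would empty a gene is rejected; total
removal is exactly `gene_loss`, so event counts are unambiguous. Third,
`domain_contraction` is deliberately distinct from `fission_domain_loss`:
losing one folB copy from a standalone `B-B` gene does not break up a
multi-domain fusion, so it should not count as a fission. This distinction
is what lets the case-study branch leading to *Aspergillus carbonarius* and
*Coccidioides immitis* carry a tandem contraction while the fission total
stays at nine (four separations + five domain losses). Internal-run
deletions (e.g. `B-K-P` → `B-P`) are grammatical and classify as
`fission_domain_loss`; they simply never occur in the case study.

## Event costs and the profile distance

Inference is weighted parsimony under a per-type cost model
(`default_costs()`): every type costs 1 except `gene_gain` at 10. The gain
penalty encodes a strong prior for vertical inheritance — a gain is only
invoked when ten ordinary events cannot explain the data. Costs are
user-overridable; raising one type's cost can never lower any distance
(tested as an invariant).

`event_distance()` runs a best-first search over the profile graph induced
by the grammar. Implementation notes:

* The search is A\* with an admissible, consistent lower bound (a domain
  symbol present in the target but absent from the current profile can only
  arrive via `gene_gain`; each event changes the gene count by at most one;
  token surpluses/deficits need at least one removing/adding event). This
  returns exactly the uniform-cost optimum, just faster.
* Ties on the frontier are broken in canonical profile-text order, making
  the reported path deterministic. All optimal paths can be enumerated
  (`all_paths = TRUE`), capped at 64 by default.
* `gene_gain` needs a concrete architecture, so a distance query has a
  **gain pool**; the default pool is the target profile's architectures.
  The distance is therefore defined *relative to a pool*; the triangle
  inequality is guaranteed when one fixed pool is used across the legs
  being compared, and the test suite checks it that way.
* `max_cost` (default 12) bounds the search. It is ample for the case
  study (whose largest realised distance is a gain plus one edit) while
  preventing runaway exploration when gains are disabled by infinite cost.
* Floating-point cost comparisons use a 1e-9 slack; with the default
  integer-valued costs this is effectively exact.

`brute_force_distance()` — plain breadth-first enumeration of all event
sequences up to a small depth — is kept in the package as the oracle the
search is tested against.

## Sankoff reconstruction on the tree

`sankoff()` (or the classed `arch_parsimony()` front end) reconstructs
ancestral profiles on a rooted tree. Because the profile space is infinite
in principle, the dynamic program runs over a finite **state universe**
(`build_universe()`): the distinct observed tip profiles (plus any root
constraint), closed under up to `depth` single events, gains excluded from
the closure. Depth is guarded (≤ 3, ≤ 5000 states). The default depth of 1
is sufficient for the case study because every ancestral state the
narrative scenario needs is itself an observed tip profile; depth 2 adds
hundreds of states and does not change the optimum there.

Transition costs between universe states are shortest paths in the
single-event graph **within the universe** (gains allowed as priced moves
when finite). Restricting paths to the universe is what makes the DP
well-defined and fast; it can only overestimate the unrestricted distance,
and for the shipped analyses the two agree on every realised branch — the
reported per-branch paths are recomputed with the unrestricted search, and
a reconstruction's `total_cost` is the sum of those path costs.

The traceback enumerates *all* most-parsimonious reconstructions up to
`max_mprs` (default 256) and flags truncation honestly: alternative
reconstructions that are equally or only slightly less parsimonious are a
finding, not a nuisance. Branch lengths are ignored by parsimony; they
drive only the simulator. Polytomies are handled, each child contributing
independently.

With default costs the Amorphea case study has minimum cost 13 — one less
than the stated 14-event narrative, e.g. by replacing independent folB
losses within Basidiomycota with a stem-level loss plus a re-expansion
elsewhere — and two optimal free-root states, `{B-K-P}` and `{B-B-K-P}`.
The package reports this tension (`strictly_below_scenario`) rather than
forcing the narrative to look optimal; the headline fission counts are a
property of the *stated scenario*, reproduced by the scenario engine, while
the inference mode answers the root-state question (the three-domain
fusion remains among the optimal roots).

## Scenarios

A scenario (`arch_scenario()`) is a root state plus an ordered list of
events addressed by the *child node* of the branch they occur on — tip
names or named internal clades (`Opisthokonta`, `Pezizomycotina`, ...), so
files stay valid when uniform clades are rearranged. `play_scenario()`
propagates the root state down the tree; `validate_scenario()` reports
per-tip matches and per-event grammar violations instead of stopping;
`summarize_scenario()` refuses invalid scenarios and otherwise returns
per-type counts (classified by the grammar, not trusted from the file) and
the scenario's cost.

## The simulator and what it does (not) emulate

`simulate_evolution()` is a continuous-time jump process run independently
along each branch: the total hazard is Σ over types of rate × (number of
applicable event instances), waiting times are exponential, and the
realised instance is chosen proportionally to its rate. Identical gene
copies each count as instances; cap-violating instances are excluded from
the applicable set rather than rejection-sampled, so hazards are always
well-defined. The default demo rates (`default_rates()`: deletion-type and
loss events 0.2, duplication and fusion 0.1, gain 0) echo the qualitative
finding that fission and loss dominate; they are demonstration values, not
estimates.

The generator emulates exactly the processes the grammar can describe, on
the stated tree with the stated branch lengths. It does **not** emulate
sequence-level reality: no alignment noise, no annotation error in domain
calls, no rate heterogeneity across lineages, no horizontal transfer unless
a gain rate and pool are supplied, and no selection linking events across
branches. Passing recovery tests therefore shows that the inference
machinery is correct *under the model*, not that real genome annotations
are error-free.

Calibration is tested against closed forms (a pure-loss branch hits
1 − e^{−λt} within three standard errors at 10,000 replicates), the event
log replays exactly to the simulated tips, and `recovery_experiment()`
asserts the parsimony lower bound — inferred minimal cost ≤ true event
cost — on every replicate, with the true history's intermediate states
added to the universe so the truth is always representable.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run, by design, at desk scale:
the 24-tip Amorphea tree with a 44-state depth-1 universe (seconds); oracle
equivalence on all rooted 4-tip shapes plus a 6-tip caterpillar over the
6 distinct case-study profiles; brute-force distance comparison at depth 4
over all ordered case-study profile pairs; 10,000 calibration replicates on
a single branch; 200 randomised distance comparisons at depth 3. Seeds are
fixed wherever randomness enters. Equal-cost alternatives are everywhere
resolved by canonical (radix) text order, so every reported object is
reproducible bit-for-bit.

## Fixture coding decisions

The case-study fixture commits to interpretations where the narrative
leaves slack, and flags them in its per-row provenance notes:
*Saccharomyces cerevisiae* is coded `B-B-K-P` (the tandem-folB form found
across fungi; required for the fission-by-loss events to be confined to
Basidiomycota); Wallemia and Laccaria are coded as having lost both folB
copies, Melampsora/Postia/Coprinopsis one; the choanoflagellate and
metazoan placeholder tips are coded pathway-absent; the interior
arrangements of the uniformly-coded Amoebozoa and of Pezizomycotina are
fixed arbitrarily (tests verify the inference is invariant to permuting a
uniform clade); the Branchiostoma `B-K` fusion (prokaryote-derived) and
the Arabidopsis xenologous standalone folB appear only in the
eukaryote-wide diversity table, not in the Amorphea parsimony set;
the long-branch microsporidian is excluded.

## Known limitations

* The event distance is exact but exponential in the worst case; it is
  intended for the small profiles (≤ 4 genes, ≤ 6 domains) the caps
  enforce.
* The universe-restricted DP can overestimate transition costs if the
  universe is too shallow; raise `universe_depth` (or supply a universe)
  when tips are separated by long multi-event paths through unobserved
  states.
* Parsimony has no notion of time: branch lengths, rate variation and
  reversals along a single branch are invisible to it. The simulator
  exists precisely to quantify that gap.
* `gene_gain` models any origination (transfer, de novo fusion import) as
  a single priced event with a stated architecture; it does not model
  donor lineages.
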