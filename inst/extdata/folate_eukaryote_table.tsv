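taxon	profile	note
Acanthamoeba_castellanii	B-K-P	three-domain folB-folK-folP fusion of the Amoebozoa
Copromyxa_protea	B-K-P	three-domain folB-folK-folP fusion of the Amoebozoa
Dictyostelium_discoideum	B-K-P	three-domain folB-folK-folP fusion of the Amoebozoa
Dictyostelium_purpureum	B-K-P	three-domain folB-folK-folP fusion of the Amoebozoa
Pygsuia_biforma	.	pterin branch absent from this breviate genome
Thecamonas_trahens	.	pterin branch absent; folate presumed salvaged
Sphaeroforma_arctica	B-B;K-P	fission product pair folB-folB + folK-folP (event F1)
Capsaspora_owczarzaki	B-B;K-P	fission product pair folB-folB + folK-folP (event F2)
Choanoflagellata_rep	.	pathway coded absent; representative placeholder tip (interpretive)
Metazoa_rep	.	complete pterin branch absent from sampled Metazoa; representative tip
Fonticula_alba	B-B-K-P	four-domain folB-folB-folK-folP fusion of this sorocarpic protist
Saccharomyces_cerevisiae	B-B-K-P	coded folB-folB-folK-folP with the fungal tandem folB; note an alternative reading as a three-domain protein exists (interpretive)
Aspergillus_carbonarius	B;K-P	standalone folB (after tandem contraction) + folK-folP
Coccidioides_immitis	B;K-P	standalone folB (after tandem contraction) + folK-folP
Cochliobolus_heterostrophus	B-B;K-P	Pezizomycotina fission products folB-folB + folK-folP (event F3)
Cladonia_grayi	B-B;K-P	Pezizomycotina fission products folB-folB + folK-folP (event F3)
Chaetomium_globosum	B-B;K-P	Pezizomycotina fission products folB-folB + folK-folP (event F3)
Neurospora_crassa	B-B;K-P	Pezizomycotina fission products folB-folB + folK-folP (event F3)
Wallemia_sebi	K-P	both folB copies lost from the fusion (FL event); folK-folP retained
Puccinia_graminis	B-B;K-P	fission product pair folB-folB + folK-folP (event F4)
Melampsora_laricis_populina	B-K-P	one folB copy lost from the fusion (FL event)
Postia_placenta	B-K-P	one folB copy lost from the fusion (FL event)
Laccaria_bicolor	K-P	both folB copies lost from the fusion (FL event)
Coprinopsis_cinerea	B-K-P	one folB copy lost from the fusion (FL event)
Branchiostoma_floridae	B-K	prokaryote-derived folB-folK HGT fusion; kept out of the Amorphea parsimony set
SAR_rep	K-P	folK-folP fusion, folB undetected across sampled SAR genomes
Cryptophyta_rep	K-P	folK-folP fusion, folB undetected
Arabidopsis_thaliana	B;K-P	folK-folP fusion + xenologous standalone folB of separate bacterial ancestry
Trypanosoma_rep	.	pathway absent; folate salvage presumed
Naegleria_rep	.	pathway absent; folate salvage presumed
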