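taxon	profile
Acanthamoeba_castellanii	B-K-P
Copromyxa_protea	B-K-P
Dictyostelium_discoideum	B-K-P
Dictyostelium_purpureum	B-K-P
Pygsuia_biforma	.
Thecamonas_trahens	.
Sphaeroforma_arctica	B-B;K-P
Capsaspora_owczarzaki	B-B;K-P
Choanoflagellata_rep	.
Metazoa_rep	.
Fonticula_alba	B-B-K-P
Saccharomyces_cerevisiae	B-B-K-P
Aspergillus_carbonarius	B;K-P
Coccidioides_immitis	B;K-P
Cochliobolus_heterostrophus	B-B;K-P
Cladonia_grayi	B-B;K-P
Chaetomium_globosum	B-B;K-P
Neurospora_crassa	B-B;K-P
Wallemia_sebi	K-P
Puccinia_graminis	B-B;K-P
Melampsora_laricis_populina	B-K-P
Postia_placenta	B-K-P
Laccaria_bicolor	K-P
Coprinopsis_cinerea	B-K-P
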