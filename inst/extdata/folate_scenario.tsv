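# root_state: B-K-P
child_node	event_type	inputs	outputs	detail
Opisthokonta	domain_duplication	B-K-P	B-B-K-P	run=1:1
Sphaeroforma_arctica	fission_separation	B-B-K-P	B-B;K-P	split=2
Capsaspora_owczarzaki	fission_separation	B-B-K-P	B-B;K-P	split=2
Pezizomycotina	fission_separation	B-B-K-P	B-B;K-P	split=2
Puccinia_graminis	fission_separation	B-B-K-P	B-B;K-P	split=2
Wallemia_sebi	fission_domain_loss	B-B-K-P	K-P	run=1:2
Laccaria_bicolor	fission_domain_loss	B-B-K-P	K-P	run=1:2
Coprinopsis_cinerea	fission_domain_loss	B-B-K-P	B-K-P	run=1:1
Postia_placenta	fission_domain_loss	B-B-K-P	B-K-P	run=1:1
Melampsora_laricis_populina	fission_domain_loss	B-B-K-P	B-K-P	run=1:1
AspergillusCoccidioides	domain_contraction	B-B	B	run=1:1
Thecamonas_trahens	gene_loss	B-K-P	.	
Pygsuia_biforma	gene_loss	B-K-P	.	
ChoanoMetazoa	gene_loss	B-B-K-P	.	
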