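case_id	phenotype	taxon	target_gene	path_label	mutation_class	n_events	evidence_type	reason
glycoside	Glycoside resistance	Aphididae	Na+/K+-ATPase (ATPalpha1)	T797A	ti	2	functional_validation	parallel occurs in both a cardenolide consumer and a non-consumer aphid; not counted as an adaptive parallel by the original curators
glycoside	Glycoside resistance	Aphididae	Na+/K+-ATPase (ATPalpha1)	N122Y	tv	2	functional_validation	parallel occurs in both a cardenolide consumer and a non-consumer aphid; not counted as an adaptive parallel by the original curators
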