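case_id	phenotype	taxon	target_gene	path_label	mutation_class	n_events	evidence_type
insecticide	Insecticide resistance	Insecta	Rdl, Kdr, Ace	insecticide.ti.1	ti	2	genetic_association
insecticide	Insecticide resistance	Insecta	Rdl, Kdr, Ace	insecticide.ti.2	ti	2	genetic_association
insecticide	Insecticide resistance	Insecta	Rdl, Kdr, Ace	insecticide.ti.3	ti	5	genetic_association
insecticide	Insecticide resistance	Insecta	Rdl, Kdr, Ace	insecticide.ti.4	ti	2	genetic_association
insecticide	Insecticide resistance	Insecta	Rdl, Kdr, Ace	insecticide.ti.5	ti	3	genetic_association
insecticide	Insecticide resistance	Insecta	Rdl, Kdr, Ace	insecticide.tv.1	tv	9	genetic_association
insecticide	Insecticide resistance	Insecta	Rdl, Kdr, Ace	insecticide.tv.2	tv	2	genetic_association
insecticide	Insecticide resistance	Insecta	Rdl, Kdr, Ace	insecticide.tv.3	tv	4	genetic_association
tetrodotoxin	Tetrodotoxin resistance	Vertebrata	Na channels	tetrodotoxin.ti.1	ti	2	functional_validation
tetrodotoxin	Tetrodotoxin resistance	Vertebrata	Na channels	tetrodotoxin.ti.2	ti	6	functional_validation
tetrodotoxin	Tetrodotoxin resistance	Vertebrata	Na channels	tetrodotoxin.ti.3	ti	3	functional_validation
tetrodotoxin	Tetrodotoxin resistance	Vertebrata	Na channels	tetrodotoxin.tv.1	tv	2	functional_validation
tetrodotoxin	Tetrodotoxin resistance	Vertebrata	Na channels	tetrodotoxin.tv.2	tv	2	functional_validation
tetrodotoxin	Tetrodotoxin resistance	Vertebrata	Na channels	tetrodotoxin.tv.3	tv	2	functional_validation
tetrodotoxin	Tetrodotoxin resistance	Vertebrata	Na channels	tetrodotoxin.tv.4	tv	3	functional_validation
tetrodotoxin	Tetrodotoxin resistance	Vertebrata	Na channels	tetrodotoxin.tv.5	tv	3	functional_validation
glycoside	Glycoside resistance	Metazoa	Na+/K+-ATPase (ATPalpha1)	G120R	ti	4	functional_validation
glycoside	Glycoside resistance	Metazoa	Na+/K+-ATPase (ATPalpha1)	Q111R	ti	4	functional_validation
glycoside	Glycoside resistance	Metazoa	Na+/K+-ATPase (ATPalpha1)	I315V	ti	2	functional_validation
glycoside	Glycoside resistance	Metazoa	Na+/K+-ATPase (ATPalpha1)	N122D	ti	2	functional_validation
glycoside	Glycoside resistance	Metazoa	Na+/K+-ATPase (ATPalpha1)	Q111L	tv	7	functional_validation
glycoside	Glycoside resistance	Metazoa	Na+/K+-ATPase (ATPalpha1)	L111V	tv	2	functional_validation
glycoside	Glycoside resistance	Metazoa	Na+/K+-ATPase (ATPalpha1)	P118A	tv	2	functional_validation
glycoside	Glycoside resistance	Metazoa	Na+/K+-ATPase (ATPalpha1)	N122H	tv	4	functional_validation
herbicide	Herbicide resistance	Poaceae	ACCase	herbicide.ti.1	ti	5	functional_validation
herbicide	Herbicide resistance	Poaceae	ACCase	herbicide.ti.2	ti	2	functional_validation
herbicide	Herbicide resistance	Poaceae	ACCase	herbicide.tv.1	tv	7	functional_validation
herbicide	Herbicide resistance	Poaceae	ACCase	herbicide.tv.2	tv	2	functional_validation
herbicide	Herbicide resistance	Poaceae	ACCase	herbicide.tv.3	tv	4	functional_validation
herbicide	Herbicide resistance	Poaceae	ACCase	herbicide.tv.4	tv	5	functional_validation
altitude	Altitude adaptation	Aves	beta-hemoglobin	altitude.ti.1	ti	4	functional_validation
altitude	Altitude adaptation	Aves	beta-hemoglobin	altitude.ti.2	ti	13	functional_validation
altitude	Altitude adaptation	Aves	beta-hemoglobin	altitude.tv.1	tv	2	functional_validation
altitude	Altitude adaptation	Aves	beta-hemoglobin	altitude.tv.2	tv	3	functional_validation
altitude	Altitude adaptation	Aves	beta-hemoglobin	altitude.tv.3	tv	2	functional_validation
vision	Trichromatic vision	Vertebrata	Opsins	vision.ti.1	ti	2	functional_validation
vision	Trichromatic vision	Vertebrata	Opsins	vision.ti.2	ti	5	functional_validation
vision	Trichromatic vision	Vertebrata	Opsins	vision.tv.1	tv	6	functional_validation
vision	Trichromatic vision	Vertebrata	Opsins	vision.tv.2	tv	4	functional_validation
vision	Trichromatic vision	Vertebrata	Opsins	vision.tv.3	tv	2	functional_validation
echolocation	Echolocation	Mammalia	Prestin	echolocation.ti.1	ti	2	functional_validation
echolocation	Echolocation	Mammalia	Prestin	echolocation.ti.2	ti	2	functional_validation
echolocation	Echolocation	Mammalia	Prestin	echolocation.ti.3	ti	2	functional_validation
echolocation	Echolocation	Mammalia	Prestin	echolocation.tv.1	tv	3	functional_validation
echolocation	Echolocation	Mammalia	Prestin	echolocation.tv.2	tv	2	functional_validation
ritonavir	Growth in ritonavir	HIV-1	Protease	ritonavir.ti.1	ti	25	functional_validation
ritonavir	Growth in ritonavir	HIV-1	Protease	ritonavir.ti.2	ti	7	functional_validation
ritonavir	Growth in ritonavir	HIV-1	Protease	ritonavir.ti.3	ti	9	functional_validation
ritonavir	Growth in ritonavir	HIV-1	Protease	ritonavir.tv.1	tv	4	functional_validation
ribonuclease	Foregut fermentation	Vertebrata	Ribonucleases	ribonuclease.ti.1	ti	2	functional_validation
ribonuclease	Foregut fermentation	Vertebrata	Ribonucleases	ribonuclease.ti.2	ti	4	functional_validation
ribonuclease	Foregut fermentation	Vertebrata	Ribonucleases	ribonuclease.ti.3	ti	4	functional_validation
benzimidazole	Benzimidazole resistance	Ascomycota	beta-tubulin	benzimidazole.ti.1	ti	7	functional_validation
benzimidazole	Benzimidazole resistance	Ascomycota	beta-tubulin	benzimidazole.tv.1	tv	5	functional_validation
benzimidazole	Benzimidazole resistance	Ascomycota	beta-tubulin	benzimidazole.tv.2	tv	6	functional_validation
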