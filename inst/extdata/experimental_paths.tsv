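case_id	phenotype	taxon	target_gene	path_label	mutation_class	n_events	evidence_type
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.1	ti	4	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.2	ti	3	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.3	ti	2	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.4	ti	2	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.5	ti	4	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.6	ti	2	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.7	ti	2	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.8	ti	3	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.9	ti	4	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.10	ti	4	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.11	ti	2	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.12	ti	2	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.13	ti	4	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.14	ti	2	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.15	ti	4	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.16	ti	3	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.ti.17	ti	2	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.tv.1	tv	2	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.tv.2	tv	3	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.tv.3	tv	2	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.tv.4	tv	4	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.tv.5	tv	3	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.tv.6	tv	3	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.tv.7	tv	2	experimental_linkage
phiX174_highT	High-temperature host adaptation	phage phiX174	genome	phiX174_highT.tv.8	tv	4	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.1	ti	3	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.2	ti	7	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.3	ti	10	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.4	ti	13	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.5	ti	16	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.6	ti	2	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.7	ti	26	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.8	ti	2	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.9	ti	24	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.10	ti	5	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.11	ti	10	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.12	ti	4	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.13	ti	12	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.14	ti	35	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.15	ti	5	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.ti.16	ti	7	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.tv.1	tv	2	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.tv.2	tv	11	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.tv.3	tv	2	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.tv.4	tv	2	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.tv.5	tv	3	experimental_linkage
lambda_J	Host-range adaptation (OmpF use)	phage lambda	J protein	lambda_J.tv.6	tv	22	experimental_linkage
paeruginosa_rif	Rifampicin resistance	Pseudomonas aeruginosa	RNA polymerase	paeruginosa_rif.ti.1	ti	4	experimental_linkage
paeruginosa_rif	Rifampicin resistance	Pseudomonas aeruginosa	RNA polymerase	paeruginosa_rif.ti.2	ti	35	experimental_linkage
paeruginosa_rif	Rifampicin resistance	Pseudomonas aeruginosa	RNA polymerase	paeruginosa_rif.ti.3	ti	2	experimental_linkage
paeruginosa_rif	Rifampicin resistance	Pseudomonas aeruginosa	RNA polymerase	paeruginosa_rif.ti.4	ti	5	experimental_linkage
paeruginosa_rif	Rifampicin resistance	Pseudomonas aeruginosa	RNA polymerase	paeruginosa_rif.ti.5	ti	2	experimental_linkage
paeruginosa_rif	Rifampicin resistance	Pseudomonas aeruginosa	RNA polymerase	paeruginosa_rif.ti.6	ti	4	experimental_linkage
paeruginosa_rif	Rifampicin resistance	Pseudomonas aeruginosa	RNA polymerase	paeruginosa_rif.ti.7	ti	9	experimental_linkage
paeruginosa_rif	Rifampicin resistance	Pseudomonas aeruginosa	RNA polymerase	paeruginosa_rif.tv.1	tv	3	experimental_linkage
paeruginosa_rif	Rifampicin resistance	Pseudomonas aeruginosa	RNA polymerase	paeruginosa_rif.tv.2	tv	3	experimental_linkage
paeruginosa_rif	Rifampicin resistance	Pseudomonas aeruginosa	RNA polymerase	paeruginosa_rif.tv.3	tv	2	experimental_linkage
paeruginosa_rif	Rifampicin resistance	Pseudomonas aeruginosa	RNA polymerase	paeruginosa_rif.tv.4	tv	3	experimental_linkage
phiX174_fitness	Increased fitness	phage phiX174	genome	phiX174_fitness.ti.1	ti	5	experimental_linkage
phiX174_fitness	Increased fitness	phage phiX174	genome	phiX174_fitness.ti.2	ti	2	experimental_linkage
phiX174_fitness	Increased fitness	phage phiX174	genome	phiX174_fitness.ti.3	ti	6	experimental_linkage
ecoli_kntase	Kanamycin resistance (thermostability)	Escherichia coli	KNTase	ecoli_kntase.tv.1	tv	7	experimental_linkage
ecoli_kntase	Kanamycin resistance (thermostability)	Escherichia coli	KNTase	ecoli_kntase.tv.2	tv	2	experimental_linkage
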