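pathway_id	name	type	m_fs	pct_fs	p_fs	m_cf	pct_cf	p_cf	m_cs	pct_cs	p_cs
ko03013	RNA transport	I	NA	NA	2.95e-05	NA	NA	NA	39	0.38	0.001
ko03040	Spliceosome	I	29	3.68	0.001	NA	NA	NA	32	3.12	0.008
ko04075	Plant hormone signal transduction	I	44	5.58	0.001	NA	NA	NA	55	5.36	7.79e-04
ko04144	Endocytosis	I	15	1.9	0.032	NA	NA	NA	18	1.75	0.040
ko00240	Pyrimidine metabolism	I	16	2.03	0.041	NA	NA	NA	20	1.95	0.035
ko03420	Nucleotide excision repair	I	8	1.01	0.055	NA	NA	NA	14	1.36	0.001
ko03440	Homologous recombination	II	6	0.76	0.006	6	0.66	0.011	6	0.58	0.019
ko03030	DNA replication	II	7	0.89	0.013	7	0.77	0.026	14	1.36	5.53e-06
ko04120	Ubiquitin mediated proteolysis	II	18	2.28	0.064	23	2.54	0.014	29	2.82	0.001
ko00250	Alanine, aspartate and glutamate metabolism	III	15	1.9	0.004	14	1.55	0.025	14	1.36	0.061
ko00062	Fatty acid elongation	III	6	0.76	0.063	8	0.88	0.016	NA	NA	NA
ko04141	Protein processing in endoplasmic reticulum	IV	NA	NA	NA	41	4.54	0.002	40	3.89	0.021
ko04712	Circadian rhythm - plant	IV	NA	NA	NA	12	1.33	0.021	13	1.27	0.024
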