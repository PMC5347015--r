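gene_id	name	log2_ratio_fast	fdr_fast	log2_ratio_slow	fdr_slow
gi|90503171	lanC-like protein 2-like	-1.12	3.45e-06	1.05	5.43e-11
gi|22259961	leucine-rich repeat extensin-like protein 4-like	1.65	4.53e-11	-2.01	1.16e-04
gi|22250752	Clock regulated protein, TIME FOR COFFEE-like	1.49	6.90e-57	-2.33	2.18e-35
gi|22225830	NA	1.44	2.04e-17	-1.69	6.08e-08
gi|22250698	NA	1.41	3.40e-28	-1.66	5.37e-13
gi|22240524	NA	1.36	1.15e-13	-1.04	9.88e-04
gi|22265151	unnamed protein product	1.33	2.23e-18	-1.13	9.17e-06
gi|22253147	DEAD-box ATP-dependent RNA helicase 42-like	1.32	1.08e-28	-1.12	1.35e-08
gi|22242137	unnamed protein product	1.16	6.30e-13	-1.27	1.14e-06
gi|22254644	glutamate synthase, putative (NADH dependent)	1.10	4.62e-08	-1.34	3.78e-05
gi|90517427	Unnamed protein	1.06	9.68e-31	-1.40	7.55e-22
gi|83979007	glutamate synthase, putative	1.04	5.75e-18	-1.03	2.19e-08
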