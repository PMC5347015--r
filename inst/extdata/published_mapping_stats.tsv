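sample	field	reads	printed_percent
control	total_reads	12413353	100.00
control	total_base_pairs	608254297	NA
control	total_mapped	8429247	67.90
control	perfect_match	6873209	55.37
control	le2_mismatch	1556038	12.54
control	unique_match	8350513	67.27
control	multi_match	78734	0.63
control	unmapped	3984106	32.10
fast	total_reads	11702598	100.00
fast	total_base_pairs	573427302	NA
fast	total_mapped	7730392	66.06
fast	perfect_match	6296355	53.80
fast	le2_mismatch	1434037	12.25
fast	unique_match	7651551	65.38
fast	multi_match	78841	0.67
fast	unmapped	3972206	33.94
slow	total_reads	11527110	100.00
slow	total_base_pairs	564828390	NA
slow	total_mapped	7579398	65.75
slow	perfect_match	6051017	52.49
slow	le2_mismatch	1528381	13.26
slow	unique_match	7505842	65.11
slow	multi_match	73556	0.64
slow	unmapped	3947712	34.25
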