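contrast	up	down	total
control_vs_fast	968	753	1721
control_vs_slow	1089	898	1987
fast_vs_slow	780	955	1735
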