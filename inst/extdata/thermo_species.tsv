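name	phase	gf0_kj_mol	hf0_kj_mol
acetate	aqueous	-369.41	-486.01
H+	proton	0	0
CH4	gas	-50.75	-74.81
CO2	gas	-394.359	-393.509
H2	gas	0	0
O2	gas	0	0
H2O	liquid-water	-237.178	-285.83
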