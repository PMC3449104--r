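x_nm	pKa_eff	kind	width_nm	Kb_L_per_mol
0.7	4	acid	0.3	0
1.2	4	acid	0.3	0
2.8	4	acid	0.3	0
3.2	4	acid	0.3	0
3.6	4	acid	0.3	0
0.5	10	base	0.3	0
1.5	10	base	0.3	0
2.6	10	base	0.3	0
3.4	10	base	0.3	0
1.8	4	acid	0.2	20
2.2	4	acid	0.2	20
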