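C_mol_per_L	gamma_pm	kappa_S_per_m
0.01	0.7382298	0.24687443
0.02	0.6794503	0.45096868
0.05	0.60355572	0.98147678
0.1	0.55627729	1.7553764
0.2	0.52817268	3.1493195
0.5	0.55109151	6.9171723
0.75	0.60636675	9.7857593
1	0.67978979	12.403332
1.5	0.87637551	16.785125
2	1.1485786	20.025862
2.5	1.5180023	22.299244
3	2.0162715	23.846169
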