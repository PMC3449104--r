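# limiting diffusion coefficients at 25 C
name	z	D_bulk_m2_per_s
K	1	1.957e-9
Na	1	1.334e-9
Cl	-1	2.032e-9
Mg	2	0.706e-9
Ca	2	0.792e-9
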