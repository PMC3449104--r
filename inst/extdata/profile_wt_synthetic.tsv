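x_nm	X_mol_per_L	A_nm2
0	0.430941007142035	1
0.05	0.538199642243985	1
0.1	0.648952842838065	1
0.15	0.754063344391017	1
0.2	0.842130172484981	1
0.25	0.900432676981222	1
0.3	0.916322793055603	1
0.35	0.878894640280917	1
0.4	0.780665413445662	1
0.45	0.618957562260829	1
0.5	0.396701340852967	1
0.55	0.122481065137919	1
0.6	-0.190193970951335	1
0.65	-0.524243771479279	1
0.7	-0.860715836228632	1
0.75	-1.1804939608608	1
0.8	-1.46572857704412	1
0.85	-1.70082606086821	1
0.9	-1.87300146905125	1
0.95	-1.97255167169138	1
1	-1.99309496849027	1
1.05	-1.93202292719027	1
1.1	-1.79132274362316	1
1.15	-1.57877607432381	1
1.2	-1.30934737448839	1
1.25	-1.00635596558874	1
1.3	-0.701798313295692	1
1.35	-0.435010138315167	1
1.4	-0.248876852265128	1
1.45	-0.183228325876248	1
1.5	-0.266039498938094	1
1.55	-0.504464523417555	1
1.6	-0.878973206217331	1
1.65	-1.34402241761766	1
1.7	-1.83705178933968	1
1.75	-2.29427418023676	1
1.8	-2.66807265522457	1
1.85	-2.93890074062367	1
1.9	-3.11603699967487	1
1.95	-3.22628474926579	1
2	-3.29559333789363	1
2.05	-3.33242722665338	1
2.1	-3.32117591477168	1
2.15	-3.22900855510276	1
2.2	-3.02286505679967	1
2.25	-2.68834028901964	1
2.3	-2.24160791720226	1
2.35	-1.72929833416959	1
2.4	-1.21707298635748	1
2.45	-0.772367103926245	1
2.5	-0.448275067895869	1
2.55	-0.273736542915216	1
2.6	-0.251648940953231	1
2.65	-0.363332062354915	1
2.7	-0.576203862363886	1
2.75	-0.851697222202732	1
2.8	-1.1516166081777	1
2.85	-1.44239963972953	1
2.9	-1.69755647550659	1
2.95	-1.89881546925142	1
3	-2.03640213225236	1
3.05	-2.10867041931777	1
3.1	-2.12115380996708	1
3.15	-2.08506021817739	1
3.2	-2.01528030412132	1
3.25	-1.9280699481932	1
3.3	-1.83866228868098	1
3.35	-1.75912829821584	1
3.4	-1.69681116275319	1
3.45	-1.65359411044953	1
3.5	-1.62612681328126	1
3.55	-1.60695633007938	1
3.6	-1.58632682227114	1
3.65	-1.55427620877607	1
3.7	-1.50260615300366	1
3.75	-1.4263495436063	1
3.8	-1.32449303265075	1
3.85	-1.19989277856838	1
3.9	-1.05849941115178	1
3.95	-0.908138349647507	1
4	-0.757147091108446	1
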