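protein_a	protein_b	confidence
Amph	Syp	0.92
Syp	Map2	0.80
Map2	Mapk3	0.70
Amph	Actr3b	0.75
Actr3b	Cap1	0.82
Amph	Ppp3ca	0.66
Ppp3ca	Ppp1cb	0.88
Amph	Dpysl5	0.60
Dpysl5	Crmp1	0.90
Mdh1	Pgk2	0.72
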