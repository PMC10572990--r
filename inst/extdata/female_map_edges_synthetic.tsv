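protein_a	protein_b	confidence
Fkbp1a	Hspa1b	0.90
Fkbp1a	Park7	0.72
Fkbp1a	Rab4a	0.61
Hspa1b	Hspa2	0.88
Hspa1b	Pdia3	0.74
Park7	Prdx1	0.81
Prdx1	Gstp1	0.76
Gstp1	Gstm1	0.85
Hspa2	Atp6v1a	0.58
Eno2	Gpi	0.83
Gpi	Pklr	0.71
Eno2	Gapdhs	0.64
Eno2	Got2	0.69
Got2	Cs	0.78
Cs	Acat1	0.80
Got2	Glul	0.57
Ppp1cc	Ppp2cb	0.86
Ppp2cb	Ppp2r1a	0.91
Ppp2r1a	Ppfia3	0.62
Thy1	Gap43	0.68
Gap43	Marcks	0.73
Dbn1	Tagln3	0.59
Dbn1	Acta1	0.66
Thy1	Dbn1	0.70
Gna12	Gnb2	0.77
Gnb2	Gnal	0.79
Fkbp1a	Eno2	0.67
Hspa1b	Eno2	0.63
Fkbp1a	Ppp1cc	0.55
Hspa1b	Thy1	0.56
Gnal	Ppfia3	0.52
Septin8	Septin10	0.84
Rab37	Bbx	0.65
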