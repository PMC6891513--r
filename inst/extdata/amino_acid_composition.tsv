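residue	total	free
Asp	17.02	0
Thr	8.10	0
Ser	6.40	0
Glu	18.71	0.038
Gly	13.42	0.29
Ala	22.20	0
Cys	0	0
Val	14.55	0
Met	0	0
Ile	11.03	0.21
Leu	15.00	0.69
Tyr	6.21	0.29
Phe	2.97	0.40
His	0.26	0
Lys	10.06	0.45
Arg	8.80	0.60
Pro	4.91	0
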