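protein	ep_log2	ep_p	ealone_log2	ealone_p
B2M	0.208	0.00205	0.230	0.00110
IGFALS	0.151	0.00785	0.143	0.0282
CFD	-0.246	0.00871	-0.0472	0.620
PRG4	0.0735	0.181	0.128	0.0327
IGFBP1	0.528	0.00242	1.270	3.66e-06
MST1	0.530	0.0100	0.633	0.00195
C9	0.101	0.0645	0.179	0.00858
SERPIND1	0.450	0.0240	0.156	0.344
C1QB	0.0113	0.465	0.0480	0.0125
ATRN	-0.190	0.000213	-0.126	0.00366
INHBE	0.258	0.0723	0.520	0.00734
CHRDL2	-0.301	0.0415	-0.000906	0.993
C8A	-0.206	0.000163	-0.202	0.000121
C2	0.334	0.00371	0.291	0.0107
GC	0.231	3.10e-06	0.237	2.75e-06
SERPINF2	0.0922	0.148	0.166	0.0247
F12	0.261	0.000102	0.252	0.000219
AFM	0.0580	0.119	0.177	0.000330
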