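protein	ep_log2	ep_p	ealone_log2	ealone_p
APOA2	0.212	0.000532	0.302	1.75e-05
PPIA	0.381	0.00899	0.201	0.126
IGFBP4	0.179	0.102	0.511	0.000697
F2	0.0633	0.00366	0.0282	0.138
C6	-0.123	0.00151	-0.171	0.000123
LILRA3	-0.237	0.00874	-0.281	0.000277
HPX	0.123	6.65e-05	0.117	0.000124
IGFBP6	0.0868	0.235	0.207	0.0158
IGFBP2	-0.420	0.00477	-0.287	0.0317
GC	0.231	3.10e-06	0.237	2.75e-06
CADM1	-0.0139	0.875	0.180	0.0249
COL1A1	-0.896	5.40e-07	-0.575	8.80e-05
COL6A3	-0.197	0.00852	-0.0134	0.834
RNASE1	0.0346	0.311	0.0953	0.0427
ITIH4	0.458	0.000733	0.374	0.00495
KLKB1	0.252	0.00208	0.230	0.00187
B2M	0.208	0.00205	0.230	0.00110
SERPINC1	-0.196	5.05e-06	-0.143	5.50e-05
FCN3	0.0351	0.0287	0.0357	0.0333
HGFAC	-0.191	0.0979	-0.308	0.00765
RBP4	0.167	0.000117	0.177	0.000262
CFHR5	0.179	0.000264	0.241	2.76e-05
PRDX2	0.691	0.0201	-0.0266	0.925
C8A	-0.206	0.000163	-0.202	0.000121
FETUB	0.783	1.09e-09	0.741	1.02e-09
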