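protein	disease	log2_ratio	p	fdr
APOA2	stroke	-0.120	2.71e-05	0.00991
PPIA	stroke	0.194	7.68e-05	0.0141
IGFBP4	stroke	0.409	0.000320	0.0391
F2	stroke	-0.0732	0.000702	0.0642
IGF2	stroke	-0.0694	0.00225	0.138
C6	stroke	-0.140	0.00227	0.138
LILRA3	stroke	0.316	0.00341	0.177
HPX	stroke	-0.0448	0.00407	0.177
IGFBP6	stroke	0.667	0.00435	0.177
LOC650157	stroke	0.237	0.00510	0.187
IGFBP2	stroke	0.480	0.00609	0.189
GC	stroke	-0.0532	0.00699	0.189
CADM1	stroke	-0.199	0.00762	0.189
PIN1	stroke	0.190	0.00767	0.189
CTSD	stroke	0.490	0.00776	0.189
COL1A1	stroke	0.195	0.00826	0.189
F13B	stroke	0.121	0.00903	0.194
MANSC1	stroke	-0.962	0.0102	0.207
COL6A3	stroke	0.828	0.0109	0.210
GRN	stroke	0.316	0.0130	0.238
RNASE1	stroke	0.582	0.0143	0.243
MTPN	stroke	0.249	0.0146	0.243
GLIPR2	stroke	0.623	0.0168	0.265
ADAMTSL2	stroke	0.205	0.0184	0.265
ITIH4	stroke	-0.238	0.0187	0.265
HLA-DRB5	stroke	0.784	0.0188	0.265
KLKB1	stroke	-0.115	0.0202	0.270
CD59	stroke	0.866	0.0208	0.270
CD14	stroke	0.104	0.0214	0.270
CSF1R	stroke	0.259	0.0223	0.272
GRB2	stroke	1.58	0.0235	0.278
CD5L	stroke	0.147	0.0253	0.289
B2M	stroke	0.0728	0.0280	0.310
SERPINC1	stroke	-0.0631	0.0312	0.325
FCN3	stroke	0.132	0.0323	0.325
HGFAC	stroke	-0.592	0.0324	0.325
RBP4	stroke	0.0478	0.0346	0.325
CFHR5	stroke	-0.0800	0.0348	0.325
PRDX2	stroke	-0.533	0.0361	0.325
C8A	stroke	-0.179	0.0373	0.325
ADAMTSL4	stroke	-0.130	0.0373	0.325
QSOX1	stroke	0.370	0.0376	0.325
CPB2	stroke	-0.228	0.0381	0.325
FETUB	stroke	0.0662	0.0410	0.332
PPIF	stroke	0.318	0.0414	0.332
LCN2	stroke	0.172	0.0417	0.332
DSC1	stroke	-0.265	0.0438	0.341
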