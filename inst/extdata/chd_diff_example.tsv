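protein	disease	log2_ratio	p	fdr
B2M	CHD	0.212	5.07e-05	0.0176
ORM1	CHD	0.120	0.000182	0.0315
IGFALS	CHD	-0.112	0.000384	0.0443
THBS1	CHD	-0.632	0.00133	0.0749
LPA	CHD	0.347	0.00138	0.0749
CFD	CHD	0.210	0.00141	0.0749
PRG4	CHD	0.232	0.00152	0.0749
GPX3	CHD	-0.224	0.00308	0.133
IGFBP1	CHD	0.423	0.00381	0.146
MST1	CHD	-0.306	0.00592	0.205
ITIH2	CHD	-0.140	0.00786	0.247
ENO1	CHD	-0.418	0.00950	0.255
C9	CHD	0.0827	0.00989	0.255
SFTPB	CHD	0.551	0.0112	0.255
FHL1	CHD	-0.481	0.0116	0.255
CRISP3	CHD	0.147	0.0118	0.255
SERPIND1	CHD	0.210	0.0176	0.334
CD5L	CHD	0.152	0.0181	0.334
SOD3	CHD	0.453	0.0183	0.334
TPI1	CHD	-0.144	0.0232	0.401
C1QB	CHD	-0.106	0.0271	0.407
ATRN	CHD	-0.151	0.0274	0.407
INHBE	CHD	0.384	0.0284	0.407
CHRDL2	CHD	-0.647	0.0287	0.407
LIMS1	CHD	-0.412	0.0318	0.407
VASP	CHD	-0.499	0.0356	0.407
C8A	CHD	0.170	0.0359	0.407
C2	CHD	-0.230	0.0361	0.407
CD14	CHD	0.105	0.0361	0.407
GC	CHD	-0.0451	0.0364	0.407
MTPN	CHD	-0.240	0.0372	0.407
SERPINF2	CHD	-0.110	0.0383	0.407
ACTA2	CHD	-1.22	0.0388	0.407
TAGLN2	CHD	-0.186	0.0426	0.433
FERMT3	CHD	-0.560	0.0462	0.454
F12	CHD	-0.147	0.0472	0.454
AFM	CHD	-0.0764	0.0490	0.458
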