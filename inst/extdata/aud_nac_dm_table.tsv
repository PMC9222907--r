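RNA	Biotype	CaseMean	ControlMean	Regulation	Log2FC	PValue	FDR
IL6	mRNA	0.660	0.293	up	1.17	0.016	0.726
RNASEH2C	mRNA	0.287	0.130	up	1.14	0.049	0.726
IL17F	mRNA	0.556	0.250	up	1.15	0.007	0.726
ZFP1	mRNA	0.371	0.163	up	1.18	0.048	0.726
TRIM60	mRNA	0.572	0.283	up	1.02	0.014	0.726
KIAA0195	mRNA	0.426	0.175	up	1.28	0.042	0.726
CA6	mRNA	0.662	0.329	up	1.01	0.038	0.726
CATSPER4	mRNA	0.458	0.224	up	1.03	0.001	0.726
GRAPL	mRNA	0.187	0.090	up	1.05	0.018	0.726
ARMC4	mRNA	0.482	0.241	up	1.00	0.045	0.726
CATG00000112871.1	mRNA	0.485	0.230	up	1.08	0.029	0.726
P2RY2	mRNA	0.524	0.254	up	1.05	0.038	0.726
SP8	mRNA	0.320	0.157	up	1.03	0.043	0.726
CHST8	mRNA	0.532	0.246	up	1.11	0.025	0.726
TMPRSS6	mRNA	0.419	0.202	up	1.05	0.037	0.726
ARSA	mRNA	0.194	0.074	up	1.40	0.011	0.726
CHAC1	mRNA	0.295	0.130	up	1.18	0.029	0.726
CDK20	mRNA	0.168	0.078	up	1.11	0.035	0.726
OR2V1	mRNA	0.623	0.274	up	1.19	0.012	0.726
OSMR	mRNA	0.737	0.345	up	1.09	0.045	0.726
H1FOO	mRNA	0.359	0.178	up	1.01	0.048	0.726
UQCRC1	mRNA	0.698	0.334	up	1.06	0.047	0.726
CATG00000071754.1	mRNA	0.429	0.177	up	1.27	0.030	0.726
INPP5B	mRNA	0.266	0.131	up	1.02	0.043	0.726
SLC12A3	mRNA	0.417	0.198	up	1.08	0.024	0.726
PSMG2	mRNA	0.358	0.177	up	1.02	0.036	0.726
PTGS2	mRNA	0.336	0.804	down	-1.26	0.005	0.726
TBCA	mRNA	0.121	0.359	down	-1.57	0.042	0.726
RPL35A	mRNA	0.232	0.538	down	-1.21	0.003	0.726
ABCG1	lncRNA	0.310	0.115	up	1.44	0.034	0.774
AC105253.1	lncRNA	0.435	0.206	up	1.08	0.002	0.774
SIX4	lncRNA	0.674	0.325	up	1.05	0.040	0.774
RP11-121J20.1	lncRNA	0.575	0.287	up	1.00	0.033	0.774
CTD-2308N23.4	lncRNA	0.165	0.424	down	-1.36	0.040	0.774
hsa-mir-4524b	miRNA	0.498	0.220	up	1.18	0.048	0.779
pri-3-hsa-mir-7157	miRNA	0.430	0.199	up	1.11	0.001	0.686
hsa-mir-1273h	miRNA	0.434	0.198	up	1.13	0.040	0.779
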