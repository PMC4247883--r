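snp_id	locus	effect_allele	other_allele	weight	ref_eaf	eaf
rs9939609	FTO	A	T	NA	0.42	0.3859
rs2867125	TMEM18	C	T	NA	0.83	0.8313
rs571312	MC4R	A	C	NA	0.24	0.2188
rs10938397	GNPDA2	G	A	NA	0.43	0.3997
rs10767664	BDNF	A	T	NA	0.78	0.8117
rs2815752	NEGR1	A	G	NA	0.61	0.7047
rs7359397	SH2B1	T	C	NA	0.4	0.1467
rs9816226	ETV5	T	A	NA	0.82	0.7757
rs3817334	MTCH2	T	C	NA	0.41	0.4338
rs29941	KCTD15	G	A	NA	0.67	0.7355
rs543874	SEC16B	G	A	NA	0.19	0.1684
rs987237	TFAP2B	G	A	NA	0.18	0.1534
rs7138803	FAIM2	A	G	NA	0.38	0.3096
rs10150332	NRXN3	C	T	NA	0.21	0.2216
rs713586	RBJ	C	T	NA	0.47	0.473
rs12444979	GPRC5B	C	T	NA	0.87	0.8946
rs2241423	MAP2K5	G	A	NA	0.78	0.7403
rs2287019	QPCTL	C	T	NA	0.8	0.8036
rs1514175	TNNI3K	A	G	NA	0.43	0.461
rs13107325	SLC39A8	T	C	NA	0.07	0.0216
rs2112347	FLJ35779	T	G	NA	0.63	0.6932
rs10968576	LRRN6C	G	A	NA	0.31	0.1224
rs3810291	TMEM160	A	G	NA	0.67	0.4874
rs11847697	PRKD1	T	C	NA	0.04	0.133
rs2890652	LRP1B	C	T	NA	0.18	0.1651
rs1555543	PTBP2	C	A	NA	0.59	0.4268
rs4771122	MTIF3	G	A	NA	0.24	0.1855
rs4929949	RPL27A	C	T	NA	0.52	0.4093
rs206936	NUDT3	G	A	NA	0.21	0.3224
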