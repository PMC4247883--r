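snp_id	weight
rs9939609	0.337779
rs2867125	0.305587
rs571312	0.277178
rs10938397	0.252107
rs10767664	0.229981
rs2815752	0.210456
rs7359397	0.193225
rs9816226	0.178019
rs3817334	0.164599
rs29941	0.152756
rs543874	0.142305
rs987237	0.133082
rs7138803	0.124943
rs10150332	0.11776
rs713586	0.111421
rs12444979	0.105827
rs2241423	0.10089
rs2287019	0.096533
rs1514175	0.092689
rs13107325	0.089296
rs2112347	0.086301
rs10968576	0.083659
rs3810291	0.081327
rs11847697	0.079269
rs2890652	0.077453
rs1555543	0.07585
rs4771122	0.074436
rs4929949	0.073187
rs206936	0.072086
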