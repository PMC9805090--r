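probe_id	chromosome	position	gene	feature	cgi_context	delta_meth	fdr
cg10070864	15	57664490		IGR	shelf	0.090	0.002
cg07199764	1	5347468		IGR	opensea	-0.113	0.004
cg19192981	15	57664704		IGR	shelf	0.085	0.004
cg07499182	13	33825496	STARD13	body	opensea	-0.064	0.005
cg25304129	22	26125490		IGR	opensea	0.050	0.010
cg17015133	1	155111332	RAG1AP1	3'UTR	shore	-0.052	0.011
cg14433904	8	78518428		IGR	opensea	0.056	0.015
cg24833027	8	1897969	ARHGEF10	body	shelf	0.067	0.019
cg00401101	5	16509323	FAM134B	TSS1500	opensea	0.060	0.021
cg08434374	11	44467306		IGR	opensea	0.057	0.022
cg03453431	7	157225567		IGR	opensea	-0.054	0.023
cg16958467	15	57655799		IGR	opensea	0.108	0.024
cg00541777	2	3652840	COLEC11	TSS1500	opensea	0.073	0.033
cg01156747	7	120659		IGR	island	-0.142	0.035
cg17322118	1	85743732	BCL10	TSS200	shore	0.053	0.035
cg12257246	8	25240570	DOCK5	body	opensea	-0.050	0.038
cg00267320	10	111533258		IGR	opensea	0.058	0.040
cg00570954	12	94281309		IGR	opensea	0.056	0.042
cg13883027	2	62892060		IGR	opensea	0.145	0.043
cg25261547	19	49363369	PLEKHA4	body	opensea	-0.052	0.046
cg21728101	7	1979360	MAD1L1	body	shore	-0.052	0.048
cg14859874	1	154238265	UBAP2L	body	opensea	-0.122	0.049
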