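probe_id	chromosome	position	delta_meth	fdr
cg10357314	11	94886261	-0.018	0.0090
cg02877698	11	94886708	-0.018	0.0087
cg10070864	15	57664490	0.090	0.0020
cg19192981	15	57664704	0.085	0.0040
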