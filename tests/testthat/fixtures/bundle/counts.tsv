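sample_id	asv_bact1	asv_bact2	asv_arch1	asv_fun1	asv_fun2
core1_d01	120	30	4	9	0
core1_d02	88	0	11	2	5
core2_d01	200	45	0	0	12
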