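sample_id	site	depth_top_cm	depth_bottom_cm	methane	sulfate	sulfide	dic	seep_status
core1_d01	core1	0	5	0.2	27.5	0.3	2.1	seep
core1_d02	core1	10	15	4.8	15.2	1.4	3.9	seep
core2_d01	core2	0	5	0.1	28.1	0.2	2.0	control
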