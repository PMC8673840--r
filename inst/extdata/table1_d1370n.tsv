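construct	quantity_kind	transition	mean	sem	n
background	dwell_time	B->IB	2000	250	6
background	dwell_time	IB->B	5100	1100	6
background	dwell_time	Cf->O	10	1.6	6
R117H	dwell_time	B->IB	67	8.8	6
R117H	dwell_time	IB->B	2800	800	6
R117H	dwell_time	Cf->O	33	5.0	6
E1124del	dwell_time	B->IB	100	16	6
E1124del	dwell_time	IB->B	4800	810	6
E1124del	dwell_time	Cf->O	23	4.0	6
R117H_E1124del	dwell_time	B->IB	58	4.4	6
R117H_E1124del	dwell_time	IB->B	3200	880	6
R117H_E1124del	dwell_time	Cf->O	50	7.9	6
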