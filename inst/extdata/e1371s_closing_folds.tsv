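construct	quantity_kind	transition	mean	sem	n
background	rate	B->IB	1	0	6
R117H	rate	B->IB	6	0	6
E1124del	rate	B->IB	6	0	6
R117H_E1124del	rate	B->IB	8.82	0	6
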