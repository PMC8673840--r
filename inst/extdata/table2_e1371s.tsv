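construct	quantity_kind	transition	mean	sem	n
background	dwell_time	Cf->O	11	2.3	6
background	dwell_time	O->Cf	200	27	6
background	equilibrium_constant	Cf<->O	17	3.9	6
R117H	dwell_time	Cf->O	58	7.3	6
R117H	dwell_time	O->Cf	11	1.1	6
R117H	equilibrium_constant	Cf<->O	0.20	0.031	6
E1124del	dwell_time	Cf->O	42	6.0	6
E1124del	dwell_time	O->Cf	18	1.7	6
E1124del	equilibrium_constant	Cf<->O	0.42	0.070	6
R117H_E1124del	dwell_time	Cf->O	150	18	6
R117H_E1124del	dwell_time	O->Cf	6.2	0.50	6
R117H_E1124del	equilibrium_constant	Cf<->O	0.042	0.0060	6
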