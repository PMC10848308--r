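station_id	snow_depth	ice_thickness	surface_par	ice_temperature	bulk_salinity	water_temperature	no3	po4	si_oh4	nh4	chlorophyll	c_to_n	delta13c_group
VM-1	14.3	92	640	-2.1	6.5	-1.71	2.10	0.20	2.50	1	0.48	6.09	LLT
VM-2	15.8	78	640	-2.2	10.7	-1.86	2.08	0.20	2.60	1	0.29	5.73	LLT
VM-3	10.0	74	640	-2.2	10.4	-1.81	2.14	0.21	2.71	1	1.90	6.02	LLT
VM-4	7.0	50	640	-2.1	3.7	-1.61	2.18	0.23	2.81	1	0.63	7.50	HLT
VM-5	4.8	52	640	-2.2	5.6	NA	2.14	0.23	2.81	1	0.86	6.92	HLT
TF-2	3.4	38	640	-2.7	9.2	-1.80	1.92	0.20	2.71	1	2.82	10.18	HLT
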