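age	total	general_pct	general_n	osteoporosis_pct	osteoporosis_n	prevalent_fx_pct	prevalent_fx_n
50	85138	0.972	82754	0.026	2214	0.002	170
60	69040	0.919	63448	0.067	4626	0.014	967
70	47455	0.885	41998	0.085	4034	0.030	1424
80	29235	0.570	16664	0.360	10525	0.070	2046
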