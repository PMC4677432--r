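age	total	general_pct	general_n	osteoporosis_pct	osteoporosis_n	prevalent_fx_pct	prevalent_fx_n
50	83691	0.933	78084	0.066	5524	0.001	84
60	70979	0.819	58132	0.163	11570	0.018	1278
70	52754	0.670	35345	0.286	15088	0.044	2321
80	41157	0.401	16504	0.472	19426	0.127	5227
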