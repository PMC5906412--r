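year	ril_mean	parent_lo_mean	parent_hi_mean	pve_pct
2014	0.78	0.57	0.92	24.30
2015	0.79	0.61	0.93	47.94
2016	0.70	0.58	0.91	19.11
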