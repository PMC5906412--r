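label	pattern	n_rils	mean_psst
HapI	DDDDDDDD	44	0.63
HapII	KKKKKKKK	29	0.91
HapIII	DDDDDDDK	92	NA
HapIV	DDDDDDKK	25	NA
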