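chrom	start	end
chr4	5830000	7910000
chr4	20560000	24640000
chr5	26010000	29950000
chr6	2530000	6440000
chr6	19480000	28910000
chr6	28930000	28970000
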