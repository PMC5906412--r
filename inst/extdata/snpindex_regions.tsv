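chrom	start	end
chr5	26700000	27370000
chr6	21840000	22070000
chr6	22140000	24450000
chr6	24480000	24700000
chr6	24750000	24830000
chr6	24980000	25150000
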