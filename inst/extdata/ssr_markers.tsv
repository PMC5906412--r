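name	chrom	start	end
RM20261	chr6	21304727	21304750
RM20356	chr6	23654188	23654207
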