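key	value
raw_reads_millions	233.62
clean_reads_millions	232.30
linkage_map_total_cM	2355.3
n_polymorphic_markers	158
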