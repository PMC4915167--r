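peak	chrom	pos_mb
first	6	88.745
second	6	88.922
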