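class	n	mean_length	total_bases
singleton	12791	598.7	7658604
contig	11653	972.0	11326166
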