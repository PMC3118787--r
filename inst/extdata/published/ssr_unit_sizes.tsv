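unit_size	count
2	1657
3	2157
4	124
5	51
6	79
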