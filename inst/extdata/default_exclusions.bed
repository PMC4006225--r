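chr15	22304999	23300000	15q11.2_BP1-BP2	0	.
chr1	145386505	146297795	1q21.1_susceptibility	0	.
chr16	29652998	30199351	16p11.2_proximal	0	.
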