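group	malate_mean	malate_sd
Ma_	7.58	1.23
mama	2.16	0.41
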