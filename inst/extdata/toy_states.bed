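1	994000	999000	1_TssA
1	999000	1002000	7_Enh
1	1002000	1006000	15_Quies
1	1006000	1010000	7_Enh
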