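CHR_ID	CHR_POS	TRAIT
1	990000	trait1
1	990000	trait2
1	1001000	trait3
1	1004750	trait4
1	1020000	trait5
2	2000000	trait6
1	NA	trait7
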