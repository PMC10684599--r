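uvmr_count	mvmr_0	mvmr_1	mvmr_2	mvmr_3
0	275	6	3	1
1	13	5	5	1
2	9	4	3	3
3	27	37	29	20
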