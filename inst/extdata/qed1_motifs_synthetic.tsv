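index	mclass	aa2	aa5	aa_last
1	L1	NA	NA	NA
2	S1	NA	NA	NA
3	P1	NA	NA	NA
4	L1	NA	NA	NA
5	S1	NA	NA	NA
6	P1	NA	NA	NA
7	L1	NA	V	N
8	S1	NA	NA	NA
9	SS	NA	T	D
10	P1	NA	NA	NA
11	L1	NA	NA	NA
12	S1	NA	NA	NA
13	P2	NA	NA	NA
14	L2	NA	NA	NA
15	S2	NA	NA	NA
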