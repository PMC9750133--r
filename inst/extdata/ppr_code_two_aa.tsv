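mclass	aa2	aa5	aa_last	nucleotides
*	*	T	N	A
*	*	T	D	G
*	*	S	N	A
*	*	S	D	G
*	*	N	D	U
*	*	N	S	C
*	*	N	N	CU
L1	*	V	N	AU
SS	*	T	D	G
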