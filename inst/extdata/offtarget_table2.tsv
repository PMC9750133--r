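genome	position	hpl6	hpl1	ubq3	ubq1	wt	site	location	impact
cp	97711	80.3	84.3	88.9	91.8	0	ndhB-291	CDS	S->L
cp	77612	40.1	48.0	86.5	87.4	0	petB_intr-mid	intron	-
cp	31530	30.6	31.2	36.3	19.3	0	trnD-psbM_intergenic	intergenic	-
cp	16335	30.2	38.8	72.2	68.7	0	rps2-203	CDS	S->L
cp	7359	10.4	13.9	0	32.9	0	trnQ_3as	intergenic, antisense	-
cp	128607	0	5.2	0	0	0	ycf1_as	antisense	-
cp	119671	0	0	30.0	44.2	0	ndhE-96	CDS	S->L
cp	33880	0	0	24.6	37.9	0	psbD_5UTR	5' UTR	-
cp	78993	0	0	17.6	7.8	0	petB-petD_intergenic	intergenic	-
cp	98961	0	0	16.6	26.6	0	ndhB-101	CDS	Q->STOP
cp	77495	0	0	16.2	34.0	0	petB_intr	intron	-
cp	124713	0	0	14.9	14.7	0	ndhH-136	CDS	R->STOP
cp	64242	0	0	13.7	0	0	ycf10-petA_intergenic	intergenic	-
cp	29881	0	0	10.4	15.0	0	petN_3UTR	3' UTR	-
cp	12570	0	0	8.4	20.3	0	atpF-65	CDS	R->STOP
cp	32653	0	0	7.7	0	0	trnE_intergenic-upstream	intergenic	-
cp	93937	0	0	6.8	0	0	ycf2_as2	antisense	-
cp	115955	0	0	5.0	0	0	rpl32-trnL_intergenic-as	intergenic, antisense	-
cp	116881	0	0	0	26.8	0	ccsA-182	CDS	S->L
cp	129614	0	0	0	14.9	0	ycf1-661	CDS	synonymous
cp	114743	0	0	0	14.7	0	rpl32_5UTR	5' UTR	-
cp	74956	0	0	0	11.8	0	psbB-27	CDS	T->I
cp	69550	0	0	0	11.5	0	psaJ_5UTR	5' UTR	-
cp	83340	0	0	0	9.7	0	rpl14-69	CDS	synonymous
cp	5800	0	0	0	9.5	0	rps16_intr	intron	-
cp	95383	0	0	0	6.7	0	ycf2-2167	CDS	Q->STOP
cp	120048	0	0	0	5.6	0	ndhG-ndhE_intergenic	intergenic	-
cp	90236	0	0	0	5.4	0	ycf2-451	CDS	P->L
cp	90203	0	0	0	5.4	0	ycf2-440	CDS	T->M
cp	90244	0	0	0	5.1	0	ycf2-454	CDS	L->F
cp	90230	0	0	0	5.1	0	ycf2_as	antisense	-
cp	61515	0	0	0	5.0	0	accD_3UTR	3' UTR	-
mt	19520	0	10.6	34.8	46.7	0	ccmC-83	CDS	H->Y
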