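affinity	site	hpl12	hpl17	ubq3	prb58
high	ndhB-291	88.2	84.3	87.5	0
high	petB_intr-mid	54.9	49.5	70	0
high	rps2-203	52.8	46.1	58.2	0
high	trnQ_3as	14.3	24.5	13.2	0
low	ndhE-96	0	0	3.5	0
low	psbD_5UTR	3.8	3.9	8	0
low	petB-petD_intergenic	0	0	2.1	0
low	ndhB-101	0	0	10.5	0
low	petB_intr	0	0	11.3	0
low	atpF-65	1.8	1.9	1.8	0
low	ccsA-182	0	0	3.2	0
low	ycf1-661	0	0	6.1	0
low	rpl32_5UTR	2.4	5.4	7.3	0
low	psbB-27	0	0	0	0
control	ndhA-358	96.9	87.3	89.1	100
control	ndhB-50	100	100	97.2	100
control	ndhD-225	91.8	86.9	82.7	100
control	rpoB-184	67.6	74	80.1	64.3
control	rps16_intr	96.8	96.8	97.7	98.3
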