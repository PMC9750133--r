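affinity	site	tc2	tc4	tc5	wt
high	ndhB-291	50.3	52.6	66.2	0
high	petB_intr-mid	68.6	68	83.8	0
high	rps2-203	26.2	27.1	48.1	0
high	trnQ_3as	0	3.1	0	0
low	ndhE-96	0	0	3.9	0
low	psbD_5UTR	4.3	2.8	0	0
low	petB-petD_intergenic	0	0	0	0
low	ndhB-101	0	6	0	0
low	petB_intr	5.5	9.9	26.2	0
low	atpF-65	0	0	0	0
low	ccsA-182	0	1.7	16.1	0
low	ycf1-661	0	0	0	0
low	rpl32_5UTR	0	0	0	0
low	psbB-27	0	0	9.3	0
control	ndhA-358	100	100	100	100
control	ndhB-50	100	100	100	100
control	ndhD-225	91.6	97.5	83.9	100
control	rpoB-184	63.3	61.9	58	53
control	rps16_intr	100	96.7	100	100
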