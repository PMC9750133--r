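ndhB-291
matK-214
rpoB-811
accD_3UTR
rps12_i1
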