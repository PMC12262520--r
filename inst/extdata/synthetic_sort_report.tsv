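replicate	bin	cell_proportion
R1	1	0.22
R1	2	0.26
R1	3	0.27
R1	4	0.25
R2	1	0.22
R2	2	0.26
R2	3	0.27
R2	4	0.25
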