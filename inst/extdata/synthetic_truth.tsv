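variant	position	class	beta_true	is_effect
p1_syn1	1	synonymous	0	FALSE
p1_mis1	1	missense	0	FALSE
p1_mis2	1	missense	0.679892076141149	TRUE
p1_mis3	1	missense	0.129994513041042	TRUE
p2_syn1	2	synonymous	0	FALSE
p2_mis1	2	missense	-1.29438561498727	TRUE
p2_mis2	2	missense	-0.848840389740529	TRUE
p2_mis3	2	missense	0	FALSE
p3_syn1	3	synonymous	0	FALSE
p3_mis1	3	missense	-0.197988140227378	TRUE
p3_mis2	3	missense	-0.0220464131629037	TRUE
p3_mis3	3	missense	0.0687053500179835	TRUE
p4_syn1	4	synonymous	0	FALSE
p4_mis1	4	missense	0	FALSE
p4_mis2	4	missense	-1.64423294801094	TRUE
p4_mis3	4	missense	0	FALSE
p5_syn1	5	synonymous	0	FALSE
p5_mis1	5	missense	0	FALSE
p5_mis2	5	missense	-0.220504156856102	TRUE
p5_mis3	5	missense	0	FALSE
p6_syn1	6	synonymous	0	FALSE
p6_mis1	6	missense	-0.409263840625041	TRUE
p6_mis2	6	missense	-0.486408577238345	TRUE
p6_mis3	6	missense	-0.670463384626598	TRUE
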