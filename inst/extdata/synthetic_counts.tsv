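variant	position	mutation	class	replicate	c1	c2	c3	c4
p1_syn1	1	syn1	synonymous	R1	99	317	149	53
p1_mis1	1	mis1	missense	R1	198	363	416	433
p1_mis2	1	mis2	missense	R1	0	16	45	465
p1_mis3	1	mis3	missense	R1	68	143	413	133
p2_syn1	2	syn1	synonymous	R1	36	318	590	440
p2_mis1	2	mis1	missense	R1	1137	60	0	0
p2_mis2	2	mis2	missense	R1	760	325	74	38
p2_mis3	2	mis3	missense	R1	37	214	104	355
p3_syn1	3	syn1	synonymous	R1	356	275	475	405
p3_mis1	3	mis1	missense	R1	92	216	554	156
p3_mis2	3	mis2	missense	R1	34	244	106	157
p3_mis3	3	mis3	missense	R1	63	352	212	122
p4_syn1	4	syn1	synonymous	R1	239	732	779	439
p4_mis1	4	mis1	missense	R1	26	842	242	180
p4_mis2	4	mis2	missense	R1	1396	0	0	0
p4_mis3	4	mis3	missense	R1	193	594	500	520
p5_syn1	5	syn1	synonymous	R1	299	105	325	276
p5_mis1	5	mis1	missense	R1	87	665	352	233
p5_mis2	5	mis2	missense	R1	135	343	110	103
p5_mis3	5	mis3	missense	R1	182	450	318	650
p6_syn1	6	syn1	synonymous	R1	88	417	222	790
p6_mis1	6	mis1	missense	R1	216	343	111	11
p6_mis2	6	mis2	missense	R1	518	299	135	61
p6_mis3	6	mis3	missense	R1	405	343	67	2
p1_syn1	1	syn1	synonymous	R2	30	262	140	677
p1_mis1	1	mis1	missense	R2	117	419	316	367
p1_mis2	1	mis2	missense	R2	0	2	16	913
p1_mis3	1	mis3	missense	R2	33	216	603	520
p2_syn1	2	syn1	synonymous	R2	168	274	341	155
p2_mis1	2	mis1	missense	R2	1148	52	91	0
p2_mis2	2	mis2	missense	R2	682	352	10	7
p2_mis3	2	mis3	missense	R2	141	112	300	281
p3_syn1	3	syn1	synonymous	R2	19	221	310	293
p3_mis1	3	mis1	missense	R2	192	660	146	247
p3_mis2	3	mis2	missense	R2	358	91	520	328
p3_mis3	3	mis3	missense	R2	17	44	176	167
p4_syn1	4	syn1	synonymous	R2	128	407	633	496
p4_mis1	4	mis1	missense	R2	216	716	452	601
p4_mis2	4	mis2	missense	R2	1273	8	0	0
p4_mis3	4	mis3	missense	R2	80	398	362	423
p5_syn1	5	syn1	synonymous	R2	109	540	150	428
p5_mis1	5	mis1	missense	R2	149	597	1029	382
p5_mis2	5	mis2	missense	R2	525	214	427	465
p5_mis3	5	mis3	missense	R2	180	570	440	361
p6_syn1	6	syn1	synonymous	R2	204	312	504	243
p6_mis1	6	mis1	missense	R2	230	456	681	45
p6_mis2	6	mis2	missense	R2	617	367	169	300
p6_mis3	6	mis3	missense	R2	744	119	79	17
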