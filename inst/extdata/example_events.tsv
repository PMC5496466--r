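onset	duration	trial_type	onset_scan	run	trial
10.72	1.5	paired_first	4	1	1
16.08	1.5	paired_second	6	1	1
32.16	1.5	isolated	12	1	2
56.28	1.5	paired_first	21	1	3
61.64	1.5	paired_second	23	1	3
77.72	1.5	isolated	29	1	4
99.16	1.5	isolated	37	1	5
120.6	1.5	isolated	45	1	6
142.04	1.5	isolated	53	1	7
166.16	1.5	paired_first	62	1	8
171.52	1.5	paired_second	64	1	8
190.28	1.5	isolated	71	1	9
211.72	1.5	isolated	79	1	10
233.16	1.5	paired_first	87	1	11
238.52	1.5	paired_second	89	1	11
254.6	1.5	paired_first	95	1	12
259.96	1.5	paired_second	97	1	12
276.04	1.5	paired_first	103	1	13
281.4	1.5	paired_second	105	1	13
297.48	1.5	isolated	111	1	14
318.92	1.5	paired_first	119	1	15
324.28	1.5	paired_second	121	1	15
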