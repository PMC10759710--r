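# per-site transition counts; `site` is 1-based (rCRS-style coordinates)
site	transitions
1	5
2	5
3	2
4	2
5	7
6	7
7	3
8	9
9	3
10	4
11	4
12	5
13	10
14	5
15	3
16	5
17	2
18	3
19	4
20	12
21	5
22	13
23	11
24	3
25	6
26	8
27	0
28	0
29	1
30	4
31	0
32	11
33	2
34	2
35	2
36	1
37	2
38	1
39	1
40	9
41	6
42	11
43	5
44	5
45	0
46	5
47	7
48	9
49	9
50	0
51	1
52	7
53	5
54	2
55	4
56	4
57	0
58	9
59	3
60	13
61	6
62	1
63	7
64	16
65	2
66	3
67	1
68	5
69	1
70	0
71	5
72	1
73	6
74	1
75	8
76	0
77	1
78	7
79	10
80	10
81	2
82	7
83	7
84	1
85	7
86	0
87	8
88	1
89	4
90	7
91	3
92	5
93	1
94	10
95	7
96	3
97	7
98	7
99	2
100	8
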