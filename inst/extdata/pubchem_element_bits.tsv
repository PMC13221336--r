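bit	z	threshold
0	1	4
1	1	8
2	1	16
3	1	32
4	3	1
5	3	2
6	5	1
7	5	2
8	5	4
9	6	2
10	6	4
11	6	8
12	6	16
13	6	32
14	7	1
15	7	2
16	7	4
17	7	8
18	8	1
19	8	2
20	8	4
21	8	8
22	8	16
23	9	1
24	9	2
25	9	4
26	11	1
27	11	2
28	14	1
29	14	2
30	15	1
31	15	2
32	15	4
33	16	1
34	16	2
35	16	4
36	16	8
37	17	1
38	17	2
39	17	4
40	17	8
41	19	1
42	19	2
43	35	1
44	35	2
45	35	4
46	53	1
47	53	2
48	53	4
49	4	1
50	12	1
51	13	1
52	20	1
53	21	1
54	22	1
55	23	1
56	24	1
57	25	1
58	26	1
59	27	1
60	28	1
61	29	1
62	30	1
63	31	1
64	32	1
65	33	1
66	34	1
67	36	1
68	37	1
69	38	1
70	39	1
71	40	1
72	41	1
73	42	1
74	44	1
75	45	1
76	46	1
77	47	1
78	48	1
79	49	1
80	50	1
81	51	1
82	52	1
83	54	1
84	55	1
85	56	1
86	71	1
87	72	1
88	73	1
89	74	1
90	75	1
91	76	1
92	77	1
93	78	1
94	79	1
95	80	1
96	81	1
97	82	1
98	83	1
99	57	1
100	58	1
101	59	1
102	60	1
103	61	1
104	62	1
105	63	1
106	64	1
107	65	1
108	66	1
109	67	1
110	68	1
111	69	1
112	70	1
113	43	1
114	92	1
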