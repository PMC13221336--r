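bit	class	size	threshold
115	any	3	1
116	sat_carbon	3	1
117	sat_nitrogen	3	1
118	sat_hetero	3	1
119	unsat_carbon	3	1
120	unsat_nitrogen	3	1
121	unsat_hetero	3	1
122	any	3	2
123	sat_carbon	3	2
124	sat_nitrogen	3	2
125	sat_hetero	3	2
126	unsat_carbon	3	2
127	unsat_nitrogen	3	2
128	unsat_hetero	3	2
129	any	4	1
130	sat_carbon	4	1
131	sat_nitrogen	4	1
132	sat_hetero	4	1
133	unsat_carbon	4	1
134	unsat_nitrogen	4	1
135	unsat_hetero	4	1
136	any	4	2
137	sat_carbon	4	2
138	sat_nitrogen	4	2
139	sat_hetero	4	2
140	unsat_carbon	4	2
141	unsat_nitrogen	4	2
142	unsat_hetero	4	2
143	any	5	1
144	sat_carbon	5	1
145	sat_nitrogen	5	1
146	sat_hetero	5	1
147	unsat_carbon	5	1
148	unsat_nitrogen	5	1
149	unsat_hetero	5	1
150	any	5	2
151	sat_carbon	5	2
152	sat_nitrogen	5	2
153	sat_hetero	5	2
154	unsat_carbon	5	2
155	unsat_nitrogen	5	2
156	unsat_hetero	5	2
157	any	5	3
158	sat_carbon	5	3
159	sat_nitrogen	5	3
160	sat_hetero	5	3
161	unsat_carbon	5	3
162	unsat_nitrogen	5	3
163	unsat_hetero	5	3
164	any	5	4
165	sat_carbon	5	4
166	sat_nitrogen	5	4
167	sat_hetero	5	4
168	unsat_carbon	5	4
169	unsat_nitrogen	5	4
170	unsat_hetero	5	4
171	any	5	5
172	sat_carbon	5	5
173	sat_nitrogen	5	5
174	sat_hetero	5	5
175	unsat_carbon	5	5
176	unsat_nitrogen	5	5
177	unsat_hetero	5	5
178	any	6	1
179	sat_carbon	6	1
180	sat_nitrogen	6	1
181	sat_hetero	6	1
182	unsat_carbon	6	1
183	unsat_nitrogen	6	1
184	unsat_hetero	6	1
185	any	6	2
186	sat_carbon	6	2
187	sat_nitrogen	6	2
188	sat_hetero	6	2
189	unsat_carbon	6	2
190	unsat_nitrogen	6	2
191	unsat_hetero	6	2
192	any	6	3
193	sat_carbon	6	3
194	sat_nitrogen	6	3
195	sat_hetero	6	3
196	unsat_carbon	6	3
197	unsat_nitrogen	6	3
198	unsat_hetero	6	3
199	any	6	4
200	sat_carbon	6	4
201	sat_nitrogen	6	4
202	sat_hetero	6	4
203	unsat_carbon	6	4
204	unsat_nitrogen	6	4
205	unsat_hetero	6	4
206	any	6	5
207	sat_carbon	6	5
208	sat_nitrogen	6	5
209	sat_hetero	6	5
210	unsat_carbon	6	5
211	unsat_nitrogen	6	5
212	unsat_hetero	6	5
213	any	7	1
214	sat_carbon	7	1
215	sat_nitrogen	7	1
216	sat_hetero	7	1
217	unsat_carbon	7	1
218	unsat_nitrogen	7	1
219	unsat_hetero	7	1
220	any	7	2
221	sat_carbon	7	2
222	sat_nitrogen	7	2
223	sat_hetero	7	2
224	unsat_carbon	7	2
225	unsat_nitrogen	7	2
226	unsat_hetero	7	2
227	any	8	1
228	sat_carbon	8	1
229	sat_nitrogen	8	1
230	sat_hetero	8	1
231	unsat_carbon	8	1
232	unsat_nitrogen	8	1
233	unsat_hetero	8	1
234	any	8	2
235	sat_carbon	8	2
236	sat_nitrogen	8	2
237	sat_hetero	8	2
238	unsat_carbon	8	2
239	unsat_nitrogen	8	2
240	unsat_hetero	8	2
241	any	9	1
242	sat_carbon	9	1
243	sat_nitrogen	9	1
244	sat_hetero	9	1
245	unsat_carbon	9	1
246	unsat_nitrogen	9	1
247	unsat_hetero	9	1
248	any	10	1
249	sat_carbon	10	1
250	sat_nitrogen	10	1
251	sat_hetero	10	1
252	unsat_carbon	10	1
253	unsat_nitrogen	10	1
254	unsat_hetero	10	1
255	aromatic	0	1
256	hetero_aromatic	0	1
257	aromatic	0	2
258	hetero_aromatic	0	2
259	aromatic	0	3
260	hetero_aromatic	0	3
261	aromatic	0	4
262	hetero_aromatic	0	4
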