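resno	bw	segment
33	1.30	TM1
34	1.31	TM1
35	1.32	TM1
36	1.33	TM1
37	1.34	TM1
38	1.35	TM1
39	1.36	TM1
40	1.37	TM1
41	1.38	TM1
42	1.39	TM1
43	1.40	TM1
44	1.41	TM1
45	1.42	TM1
46	1.43	TM1
47	1.44	TM1
48	1.45	TM1
49	1.46	TM1
50	1.47	TM1
51	1.48	TM1
52	1.49	TM1
53	1.50	TM1
54	1.51	TM1
55	1.52	TM1
56	1.53	TM1
57	1.54	TM1
58	1.55	TM1
59	1.56	TM1
60	1.57	TM1
61	1.58	TM1
62	1.59	TM1
63	1.60	TM1
68	2.38	TM2
69	2.39	TM2
70	2.40	TM2
71	2.41	TM2
72	2.42	TM2
73	2.43	TM2
74	2.44	TM2
75	2.45	TM2
76	2.46	TM2
77	2.47	TM2
78	2.48	TM2
79	2.49	TM2
80	2.50	TM2
81	2.51	TM2
82	2.52	TM2
83	2.53	TM2
84	2.54	TM2
85	2.55	TM2
86	2.56	TM2
87	2.57	TM2
88	2.58	TM2
89	2.59	TM2
90	2.60	TM2
91	2.61	TM2
92	2.62	TM2
93	2.63	TM2
94	2.64	TM2
95	2.65	TM2
96	2.66	TM2
103	3.22	TM3
104	3.23	TM3
105	3.24	TM3
106	3.25	TM3
107	3.26	TM3
108	3.27	TM3
109	3.28	TM3
110	3.29	TM3
111	3.30	TM3
112	3.31	TM3
113	3.32	TM3
114	3.33	TM3
115	3.34	TM3
116	3.35	TM3
117	3.36	TM3
118	3.37	TM3
119	3.38	TM3
120	3.39	TM3
121	3.40	TM3
122	3.41	TM3
123	3.42	TM3
124	3.43	TM3
125	3.44	TM3
126	3.45	TM3
127	3.46	TM3
128	3.47	TM3
129	3.48	TM3
130	3.49	TM3
131	3.50	TM3
132	3.51	TM3
133	3.52	TM3
134	3.53	TM3
135	3.54	TM3
136	3.55	TM3
147	4.39	TM4
148	4.40	TM4
149	4.41	TM4
150	4.42	TM4
151	4.43	TM4
152	4.44	TM4
153	4.45	TM4
154	4.46	TM4
155	4.47	TM4
156	4.48	TM4
157	4.49	TM4
158	4.50	TM4
159	4.51	TM4
160	4.52	TM4
161	4.53	TM4
162	4.54	TM4
163	4.55	TM4
164	4.56	TM4
165	4.57	TM4
166	4.58	TM4
167	4.59	TM4
168	4.60	TM4
169	4.61	TM4
170	4.62	TM4
171	4.63	TM4
196	5.35	TM5
197	5.36	TM5
198	5.37	TM5
199	5.38	TM5
200	5.39	TM5
201	5.40	TM5
202	5.41	TM5
203	5.42	TM5
204	5.43	TM5
205	5.44	TM5
206	5.45	TM5
207	5.46	TM5
208	5.47	TM5
209	5.48	TM5
210	5.49	TM5
211	5.50	TM5
212	5.51	TM5
213	5.52	TM5
214	5.53	TM5
215	5.54	TM5
216	5.55	TM5
217	5.56	TM5
218	5.57	TM5
219	5.58	TM5
220	5.59	TM5
221	5.60	TM5
222	5.61	TM5
223	5.62	TM5
224	5.63	TM5
225	5.64	TM5
226	5.65	TM5
227	5.66	TM5
228	5.67	TM5
229	5.68	TM5
234	6.30	TM6
235	6.31	TM6
236	6.32	TM6
237	6.33	TM6
238	6.34	TM6
239	6.35	TM6
240	6.36	TM6
241	6.37	TM6
242	6.38	TM6
243	6.39	TM6
244	6.40	TM6
245	6.41	TM6
246	6.42	TM6
247	6.43	TM6
248	6.44	TM6
249	6.45	TM6
250	6.46	TM6
251	6.47	TM6
252	6.48	TM6
253	6.49	TM6
254	6.50	TM6
255	6.51	TM6
256	6.52	TM6
257	6.53	TM6
258	6.54	TM6
259	6.55	TM6
260	6.56	TM6
261	6.57	TM6
262	6.58	TM6
263	6.59	TM6
264	6.60	TM6
265	6.61	TM6
278	7.30	TM7
279	7.31	TM7
280	7.32	TM7
281	7.33	TM7
282	7.34	TM7
283	7.35	TM7
284	7.36	TM7
285	7.37	TM7
286	7.38	TM7
287	7.39	TM7
288	7.40	TM7
289	7.41	TM7
290	7.42	TM7
291	7.43	TM7
292	7.44	TM7
293	7.45	TM7
294	7.46	TM7
295	7.47	TM7
296	7.48	TM7
297	7.49	TM7
298	7.50	TM7
299	7.51	TM7
300	7.52	TM7
301	7.53	TM7
302	7.54	TM7
303	7.55	TM7
304	7.56	TM7
305	8.47	H8
306	8.48	H8
307	8.49	H8
308	8.50	H8
309	8.51	H8
310	8.52	H8
311	8.53	H8
312	8.54	H8
313	8.55	H8
314	8.56	H8
315	8.57	H8
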