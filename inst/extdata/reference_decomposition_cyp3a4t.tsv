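resnum	resname	normal_mean	normal_std	cooperative_mean	cooperative_std	srs_region
57	Phenylalanine	-0.79	0.38	-0.96	0.33	1
106	Arginine	-0.89	0.33	-2.79	0.76	1
108	Phenylalanine	-0.86	0.27	0.04	0.05	1
212	Arginine	-1.75	0.37	-1.71	0.29	2 and 3
215	Phenylalanine	-2.03	0.35	-1.76	0.30	2 and 3
301	Isoleucine	-0.80	0.20	-0.71	0.18	4
304	Phenylalanine	-1.56	0.34	-2.14	0.31	4
305	Alanine	-0.94	0.25	-1.30	0.26	4
308	Glutamic acid	-0.92	0.37	-0.62	0.34	4
309	Threonine	-1.34	0.29	-1.19	0.47	4
369	Isoleucine	-1.39	0.32	-1.63	0.33	5
370	Alanine	-1.59	0.37	-1.04	0.41	5
371	Methionine	-0.26	0.07	-1.24	0.36	5
372	Arginine	-4.31	0.69	-4.25	0.79	5
373	Leucine	-0.83	0.17	-0.38	0.11	5
374	Glutamic acid	-1.09	0.70	-1.35	0.45	5
482	Leucine	-1.03	0.22	-0.60	0.15	6
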