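resnum	resname	normal_mean	normal_std	cooperative_mean	cooperative_std	srs_region
57	Phenylalanine	-0.83	0.25	-0.24	0.22	1
105	Arginine	-0.19	0.13	-2.41	0.58	1
106	Arginine	-0.80	0.33	-0.70	0.20	1
108	Phenylalanine	-0.73	0.24	0.06	0.03	1
119	Serine	-0.42	0.28	-0.78	0.46	1
212	Arginine	-3.10	0.66	-3.83	1.00	2 and 3
215	Phenylalanine	-1.89	0.39	-0.43	0.22	2 and 3
301	Isoleucine	-0.64	0.26	-0.46	0.14	4
304	Phenylalanine	-1.56	0.42	-1.07	0.33	4
305	Alanine	-1.42	0.17	-1.30	0.26	4
309	Threonine	-0.77	0.21	-0.37	0.36	4
369	Isoleucine	-1.12	0.43	-0.95	0.28	5
370	Alanine	-0.73	0.17	-1.19	0.46	5
371	Methionine	-1.75	0.29	-0.30	0.07	5
372	Arginine	-4.49	0.58	-1.86	0.59	5
373	Leucine	-0.78	0.17	-1.56	0.41	5
374	Glutamic acid	2.48	0.79	0.44	0.56	5
482	Leucine	-1.24	0.49	-2.26	0.36	6
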