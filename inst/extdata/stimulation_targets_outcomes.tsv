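patient	x	y	z	depth_mm	rmt_pct	bsi_reduction	hamd17_reduction	madrs_reduction
1	-26	45	28	20.49	65	0.22	0.64	0.54
2	-26	48	25	22.76	55	1.00	0.76	0.68
3	-29	49	32	24.86	25	1.00	0.59	0.62
4	-36	44	34	17.48	70	0.45	0.68	0.63
5	-27	50	23	22.34	30	1.00	0.79	0.78
6	-25	53	20	19.11	65	1.00	0.84	0.73
7	-40	52.5	4	21.53	45	0.72	0.74	0.60
8	-42	52	13	25.24	55	0.90	0.89	0.75
9	-32	21	40	21.15	55	0.50	0.48	0.46
10	-41	53	3	29.46	60	0.84	0.68	0.66
11	-26	48	27	20.67	60	0.83	0.83	0.83
12	-31	50	33	24.75	60	0.43	0.78	0.64
13	-40	50	1	21.92	70	0.36	0.81	0.84
14	-26	55	28	24.63	70	0.56	0.89	0.69
15	-30	48	34	17.79	35	0.47	0.86	0.78
16	-29	45	32	17.93	30	0.88	0.66	0.83
17	-41	52	8	17.91	60	0.44	0.59	0.26
18	-26	44	30	22.35	45	0.88	0.71	0.53
19	-30	48	35	23.17	70	1.00	0.77	0.83
20	-28	52	25	20.38	45	0.60	0.41	0.33
21	-28	48	32	20.45	70	0.33	0.69	0.59
22	-40	53	6	25.88	70	0.39	0.25	0.20
23	-30	38	30	17.59	75	0.44	0.75	0.50
24	-27	54	24	20.75	55	0.52	0.46	0.51
25	-36	33	37	16.78	60	0.33	0.59	0.58
26	-39	53	-1	17.95	45	0.28	0.34	0.31
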