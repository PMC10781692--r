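scale	timepoint	mean	sd
BSI-CV	baseline	17.63	7.06
BSI-CV	post	6.13	5.98
BSI-CV	week2	5.81	6.01
BSI-CV	week4	3.39	4.53
HAMD-17	baseline	27.91	4.31
HAMD-17	post	9.36	5.43
HAMD-17	week2	7.84	4.57
HAMD-17	week4	5.72	4.24
MADRS	baseline	36.69	4.49
MADRS	post	15.06	7.24
MADRS	week2	11.28	5.67
MADRS	week4	8.45	5.17
BDI	baseline	35.75	9.17
BDI	post	21.41	10.92
BDI	week2	19.44	10.33
BDI	week4	14.33	7.75
HAMD-6	baseline	13.63	2.17
HAMD-6	post	4.41	2.66
PDQ-D	baseline	42.13	15.65
PDQ-D	post	30.22	17.27
DST	baseline	13.50	2.31
DST	post	14.88	2.54
DSST	baseline	55.19	11.60
DSST	post	63.63	11.89
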