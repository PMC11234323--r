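mode	subs	power
single	0	0
single	1	0
single	2	0
single	3	0
single	4	0.0476
single	5	0.0476
single	6	0.2414
single	7	0.2414
single	8	0.4286
single	9	0.6
single	10	0.6
single	11	0.6667
single	12	0.8333
single	13	0.8889
single	14	0.9121
single	15	0.9121
single	16	0.9121
single	17	0.9121
single	18	0.9121
single	19	0.9121
single	20	0.9615
single	21	0.9615
single	22	1
single	23	1
single	24	1
single	25	1
single	26	1
single	27	1
single	28	1
single	29	1
single	30	1
single	31	1
single	32	1
single	33	1
double	0	0
double	1	0.1053
double	2	0.1143
double	3	0.4211
double	4	0.7021
double	5	0.9302
double	6	0.9444
double	7	1
double	8	1
double	9	1
double	10	1
double	11	1
double	12	1
double	13	1
double	14	1
double	15	1
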