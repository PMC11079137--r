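Branches	Genes	Sites	AA_change	Observed	Expected	p_value
a vs. b	GPX3	216	R-Q	1	0	0
a vs. e	SOD1	26	T/N-S	3	0	0
a vs. e	GPX1	201	G-E	3	0	0
a vs. e	GPX3	42	E-D	3	0	0
a vs. f	SOD3	60	A-G	4	0	0
a vs. f	GPX1	28	A-T	4	0	0
a vs. f	GPX2	14	I-V	4	0	0
a vs. f	GPX3	213	Y-H	4	0	0
a vs. g	SOD1	41	I-V	7	0	0
a vs. g	SOD1	42	M-L	7	0	0
a vs. g	CAT	423	T-A	7	0	0
a vs. g	CAT	449	K-Q	7	0	0
a vs. g	CAT	513	V-M	7	0	0
a vs. g	SOD2	57	A-T	7	0	0
a vs. g	SOD3	107	E-Q	7	0	0
a vs. i	SOD3	215	C-S	1	0	0
a vs. j	GPX3	42	E-D	1	0	0
a vs. o	CAT	293	P-Q	4	0	0
a vs. o	CAT	379	Y-F	4	0	0
a vs. o	SOD1	152	A-T	4	0	0
a vs. o	GPX2	126	Y-H	4	0	0
b vs. e	CAT	381	A-T	4	0	0
b vs. e	SOD3	76	A-E	4	0	0
b vs. e	SOD3	161	Y-H	4	0	0
b vs. e	GPX1	54	C-G	4	0	0
b vs. f	CAT	42	M-L	2	0	0
b vs. f	CAT	455	Q-E	2	0	0
b vs. g	SOD3	161	Y-H	2	0	0
b vs. g	SOD3	163	A-P	2	0	0
b vs. i	SOD3	161	Y-H	2	0	0
b vs. i	GPX1	204	C-S	2	0	0
b vs. o	CAT	254	S-A	2	0	0
b vs. o	GPX1	204	C-S	2	0	0
c vs. f	GPX1	16	P-A	1	0	0
c vs. g	GPX1	137	A-V	1	0	0
c vs. o	CAT	159	I-L	2	0	0
c vs. o	GPX1	89	A-T	2	0	0
d vs. e	SOD3	57	G-D	1	0	0
d vs. f	GPX1	16	P-A	1	0	0
e vs. f	CAT	423	T-S	3	0	0
e vs. f	CAT	427	G-A	3	0	0
e vs. f	CAT	502	A-T	3	0	0
e vs. g	CAT	256	E-U	5	0	0
e vs. g	CAT	502	A-T	5	0	0
e vs. g	SOD2	11	R-G	5	0	0
e vs. g	SOD3	161	Y-H	5	0	0
e vs. g	GPX1	199	S-A	5	0	0
e vs. i	SOD3	161	Y-H	2	0	0
e vs. i	GPX2	43	T-S	2	0	0
e vs. j	GPX3	42	E-D	2	0	0
e vs. j	GPX3	203	V-I	2	0	0
e vs. l	SOD3	57	G-D	1	0	0
e vs. m	SOD3	57	G-D	1	0	0
e vs. o	CAT	93	R-K	1	0	0
f vs. g	GPX2	92	G-S	1	0	0
f vs. k	CAT	508	A-T	2	0	0
f vs. k	SOD1	96	N-E	2	0	0
f vs. o	CAT	226	N-K	1	0	0
g vs. i	SOD3	161	Y-H	1	0	0
h vs. j	SOD1	36	T-R	1	0	0
i vs. j	GPX3	204	S-N	1	0	0
i vs. k	GPX3	192	I-V	1	0	0
i vs. o	CAT	436	N-D	2	0	0
i vs. o	GPX1	204	C-S	2	0	0
l vs. m	GPX1	204	C-A	1	0	0
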