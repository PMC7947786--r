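no	dop_msm	dop_ac	dop_grade	pafa_msm	pafa_cg	pafa_grade	note
3	S27	S27	9	A30	A37	9	.
4	V31	V31	8	F34	F41	9	.
del	A43-V79	.	.	.	.	.	dop_loop
5	A81	L80	7	S43	S50	9	a
6	A82	A81	8	S44	S51	9	a
7	I85	I84	8	F47	F54	9	.
9	V94	V93	9	L56	L63	9	b
10	ins	.	.	V58	V65	9	b
11	H96	H95	9	G59	G66	9	b
12	A97	A96	9	S60	S67	9	b
13	S102	S101	9	A65	A72	9	.
14	A103	T102	7	T66	T73	9	.
15	P104	P103	9	A67	A74	9	.
25	Y209	F208	8	H174	H188	8	c
26	E211	E210	9	W176	W190	7	c
27	V212	V211	8	E177	E191	9	c
28	E213	E212	8	G178	G192	7	c
29	G215	G214	9	S180	S194	9	c
30	L216	L215	9	S181	S195	9	c
31	E217	E216	9	A182	A196	9	c
32	L220	L219	8	R185	R199	9	c
33	K221	K220	8	S186	S200	9	c
46	S450	S452	8	D418	D439	9	.
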