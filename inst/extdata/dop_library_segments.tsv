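segment	name	kind	start	end	replacement	base_res
1	S27A	substitution	27	27	A	S
1	V31F	substitution	31	31	F	V
2	I85F	substitution	85	85	F	I
3	V94L	substitution	94	94	L	V
3	ins94V	insertion	94	94	V
3	H96G	substitution	96	96	G	H
3	A97S	substitution	97	97	S	A
4	S102A	substitution	102	102	A	S
4	A103T	substitution	103	103	T	A
4	P104A	substitution	104	104	A	P
5	S450D	substitution	450	450	D	S
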