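class	A	B	C	D
A	9	2	1	0
B	3	18	8	3
C	5	3	20	5
D	4	3	6	8
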