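class	A	B	C	D
A	37	3	0	4
B	3	74	11	6
C	5	5	77	4
D	4	7	3	47
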