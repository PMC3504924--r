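class	A	B	C	D
A	38	1	2	3
B	4	75	8	7
C	3	2	83	3
D	2	3	4	52
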