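from	to
0	O
O	0
1	I
I	1
1	L
L	1
5	S
S	5
8	B
B	8
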