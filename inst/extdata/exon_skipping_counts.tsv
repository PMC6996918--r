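pattern	total	iso1	iso1_antisense
1	591	278	191
2	13	5	1
3	4	4	4
4	500	217	155
5	59	18	7
6	71	51	51
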