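time	ne
12000	1.0
10600	1.0
8200	10.1
4100	10.1
2300	776.69
0	776.69
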