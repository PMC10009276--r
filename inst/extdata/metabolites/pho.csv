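t_min,value
0,7.4
2.5,7.25
5,7.1
7.5,6.95
10,6.8
15,6.6
20,6.45
25,6.3
30,6.2
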