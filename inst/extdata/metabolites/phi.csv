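t_min,value
0,7.2
2.5,7.05
5,6.9
7.5,6.75
10,6.6
15,6.4
20,6.25
25,6.1
30,6.0
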