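t_min,value
0,15
2.5,35
5,55
10,80
15,95
20,105
25,115
30,125
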