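t_min,value
0,15
1,40
2.5,70
4,95
6,110
8,115
10,112
12,105
15,100
20,110
25,125
30,140
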