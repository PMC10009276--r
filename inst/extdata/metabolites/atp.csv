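t_min,value
0,10
1,9.75
2.5,9.4
5,8.5
7.5,7.3
10,6.2
12.5,5.5
15,5.0
20,4.3
25,3.8
30,3.5
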