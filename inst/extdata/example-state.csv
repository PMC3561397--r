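agent_id,type,action
0,C,0
1,R,0
2,R,0
3,R,0
4,C,0
5,R,0
6,C,0
7,C,1
8,C,0
9,R,0
10,C,1
11,R,0
12,R,0
13,C,0
14,R,0
15,R,1
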