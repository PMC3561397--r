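0 12
1 2
2 3
3 4
4 5
5 9
6 7
7 8
8 9
9 10
10 11
11 12
12 13
13 14
14 15
15 0
0 2
1 3
2 4
3 5
4 6
5 7
6 8
7 9
8 10
9 4
10 12
11 13
12 14
13 15
14 0
15 1
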