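ID,TIME,DV
1,0,10.6800
1,1,3.6837
2,0,10.4020
2,1,6.4540
3,0,9.8814
3,1,5.8565
4,0,9.3408
4,1,5.6209
5,0,10.0820
5,1,6.7583
6,0,9.8938
6,1,6.5049
7,0,9.8908
7,1,6.9557
8,0,10.2340
8,1,6.4488
9,0,9.9882
9,1,6.7112
10,0,9.6736
10,1,6.6402
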