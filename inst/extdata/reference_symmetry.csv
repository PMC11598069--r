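individual,E1,E2,E3,E4,E5,E6,E7,E8
1,1.5,1.7,2.1,2.4,2.3,7.7,1.0,5.7
2,1.5,3.7,4.5,2.1,1.1,0.6,2.9,3.7
3,2.0,0.8,1.9,3.2,3.5,7.3,1.6,1.6
4,3.0,0.8,1.8,1.4,0.3,3.5,3.5,3.3
5,3.1,6.2,6.7,3.8,3.8,2.9,1.6,0.6
6,4.8,3.6,5.1,5.8,3.6,7.0,1.3,3.0
7,0.5,0.7,1.5,3.9,2.5,1.3,0.8,1.9
8,3.9,3.1,3.7,0.8,3.2,3.8,4.2,7.6
9,2.9,4.8,5.9,4.7,5.9,2.5,1.5,0.9
10,2.5,5.7,0.8,5.6,0.1,4.0,2.3,0.5
11,0.1,3.9,4.7,2.3,2.9,1.2,1.6,4.4
12,1.3,2.5,1.8,1.1,2.0,0.8,4.5,3.0
13,0.7,3.5,0.8,4.0,1.3,4.7,1.8,1.6
14,4.3,0.6,1.4,7.5,3.6,4.6,7.3,3.4
15,1.0,1.0,2.0,1.0,1.3,0.4,0.8,1.3
16,1.4,1.7,4.0,3.6,0.6,1.7,1.3,5.5
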