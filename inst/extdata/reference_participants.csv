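individual_id,age,gender,height_cm,bmi
1-AP,75,m,187,27.7
2-HCH,45,f,152,21.6
3-AM,21,f,173,18.0
4-DM,21,m,184,21.6
5-DDM,47,m,178,26.5
6-DH,24,m,185,22.8
7-JH,21,m,176,22.3
8-JM,69,m,185,27.5
9-LN,22,m,182,19.0
10-VM,47,f,163,25.6
11-MS,34,m,192,27.1
12-AB,47,m,176,22.6
13-TT,22,f,175,24.5
14-KA,8,f,135,21.6
15-T2,22,f,175,24.5
16-H2,46,f,152,21.6
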