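month,survival_fraction
1,0.776600000000001
2,0.585000000000001
3,0.4411
4,0.346299999999999
5,0.283199999999999
6,0.241799999999999
7,0.208799999999999
8,0.184099999999999
9,0.1636
10,0.1484
11,0.1325
12,0.1213
13,0.1113
14,0.1027
15,0.0956999999999996
16,0.0898999999999996
17,0.0856999999999996
18,0.0804999999999996
19,0.0752999999999996
20,0.0708999999999997
21,0.0667999999999997
22,0.0639999999999997
23,0.0611999999999997
24,0.0586999999999998
25,0.0570999999999998
26,0.0547999999999998
27,0.0519999999999998
28,0.0499999999999998
29,0.0479999999999998
30,0.0457999999999998
31,0.0442999999999998
32,0.0428999999999998
33,0.0406999999999998
34,0.0390999999999999
35,0.0381999999999999
36,0.0370999999999999
37,0.0361999999999999
38,0.0351999999999999
39,0.0347999999999999
40,0.0340999999999999
41,0.0332999999999999
42,0.0326999999999999
43,0.0319999999999999
44,0.0311999999999999
45,0.0303999999999999
46,0.0298999999999999
47,0.0291999999999999
48,0.0282999999999999
49,0.0274999999999999
50,0.0269999999999999
51,0.0264999999999999
52,0.0259999999999999
53,0.0254999999999999
54,0.0249999999999999
55,0.0245999999999999
56,0.0237999999999999
57,0.0230999999999999
58,0.0226999999999999
59,0.0221999999999999
60,0.0218999999999999
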