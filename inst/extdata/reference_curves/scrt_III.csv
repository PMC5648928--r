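month,survival_fraction
1,0.9045
2,0.9037
3,0.9028
4,0.9018
5,0.9004
6,0.8991
7,0.893600000000001
8,0.8667
9,0.8183
10,0.758000000000001
11,0.694700000000001
12,0.637200000000001
13,0.586800000000001
14,0.541600000000001
15,0.4998
16,0.4652
17,0.4353
18,0.4076
19,0.382299999999999
20,0.360299999999999
21,0.341599999999999
22,0.323499999999999
23,0.306499999999999
24,0.290499999999999
25,0.278399999999999
26,0.267599999999999
27,0.256999999999999
28,0.246499999999999
29,0.236299999999999
30,0.227899999999999
31,0.220899999999999
32,0.212899999999999
33,0.206699999999999
34,0.199699999999999
35,0.192599999999999
36,0.1886
37,0.1836
38,0.1789
39,0.1752
40,0.1705
41,0.1672
42,0.1623
43,0.1586
44,0.1543
45,0.1513
46,0.148199999999999
47,0.144099999999999
48,0.140399999999999
49,0.1375
50,0.1342
51,0.1306
52,0.1276
53,0.1259
54,0.1233
55,0.1224
56,0.1206
57,0.1176
58,0.1158
59,0.1132
60,0.1116
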