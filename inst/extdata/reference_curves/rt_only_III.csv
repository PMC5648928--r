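month,survival_fraction
1,0.9078
2,0.9065
3,0.9036
4,0.9005
5,0.892800000000001
6,0.863
7,0.7967
8,0.709800000000001
9,0.6286
10,0.556000000000001
11,0.4955
12,0.445
13,0.399699999999999
14,0.367499999999999
15,0.337699999999999
16,0.306199999999999
17,0.284499999999999
18,0.265199999999999
19,0.247599999999999
20,0.232899999999999
21,0.220099999999999
22,0.207599999999999
23,0.198099999999999
24,0.1891
25,0.1805
26,0.1708
27,0.1637
28,0.156799999999999
29,0.1503
30,0.143999999999999
31,0.138999999999999
32,0.1329
33,0.1287
34,0.1239
35,0.1194
36,0.1162
37,0.113
38,0.1093
39,0.1063
40,0.1034
41,0.0998999999999996
42,0.0977999999999996
43,0.0944999999999996
44,0.0918999999999996
45,0.0895999999999996
46,0.0873999999999996
47,0.0853999999999996
48,0.0837999999999997
49,0.0818999999999996
50,0.0806999999999996
51,0.0794999999999997
52,0.0773999999999996
53,0.0756999999999997
54,0.0748999999999997
55,0.0725999999999997
56,0.0703999999999997
57,0.0687999999999997
58,0.0675999999999997
59,0.0665999999999997
60,0.0655999999999997
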