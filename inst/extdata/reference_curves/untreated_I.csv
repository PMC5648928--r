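month,survival_fraction
1,0.999
2,0.9861
3,0.9289
4,0.8408
5,0.741200000000001
6,0.6583
7,0.585700000000001
8,0.5252
9,0.478
10,0.4341
11,0.399099999999999
12,0.365999999999999
13,0.337599999999999
14,0.313799999999999
15,0.292199999999999
16,0.275499999999999
17,0.259999999999999
18,0.244299999999999
19,0.232399999999999
20,0.221699999999999
21,0.211699999999999
22,0.203399999999999
23,0.194499999999999
24,0.185099999999999
25,0.1771
26,0.1704
27,0.1623
28,0.1561
29,0.1511
30,0.146299999999999
31,0.140399999999999
32,0.1369
33,0.1334
34,0.1295
35,0.126
36,0.1215
37,0.1167
38,0.1139
39,0.1109
40,0.1082
41,0.1046
42,0.1026
43,0.1003
44,0.0983999999999996
45,0.0958999999999996
46,0.0928999999999996
47,0.0908999999999996
48,0.0884999999999996
49,0.0863999999999996
50,0.0845999999999996
51,0.0828999999999996
52,0.0818999999999996
53,0.0800999999999996
54,0.0779999999999996
55,0.0764999999999996
56,0.0754999999999997
57,0.0736999999999997
58,0.0720999999999997
59,0.0707999999999997
60,0.0694999999999997
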