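month,survival_fraction
1,0.931500000000001
2,0.8411
3,0.736600000000001
4,0.634500000000001
5,0.552300000000001
6,0.4821
7,0.4241
8,0.376099999999999
9,0.339499999999999
10,0.309699999999999
11,0.284599999999999
12,0.263899999999999
13,0.245299999999999
14,0.228599999999999
15,0.212899999999999
16,0.199899999999999
17,0.1893
18,0.1803
19,0.1686
20,0.1581
21,0.1499
22,0.141599999999999
23,0.1341
24,0.1282
25,0.1246
26,0.1188
27,0.1148
28,0.1114
29,0.1083
30,0.1044
31,0.1019
32,0.0981999999999996
33,0.0946999999999996
34,0.0923999999999996
35,0.0897999999999996
36,0.0875999999999996
37,0.0859999999999996
38,0.0834999999999996
39,0.0816999999999996
40,0.0795999999999996
41,0.0778999999999996
42,0.0763999999999996
43,0.0744999999999997
44,0.0723999999999997
45,0.0705999999999997
46,0.0686999999999997
47,0.0669999999999997
48,0.0651999999999997
49,0.0640999999999997
50,0.0617999999999997
51,0.0604999999999997
52,0.0587999999999998
53,0.0577999999999998
54,0.0563999999999998
55,0.0552999999999998
56,0.0540999999999998
57,0.0530999999999998
58,0.0516999999999998
59,0.0508999999999998
60,0.0494999999999998
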