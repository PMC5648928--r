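month,survival_fraction
1,0.916
2,0.7979
3,0.6653
4,0.555800000000001
5,0.4678
6,0.4047
7,0.356999999999999
8,0.318699999999999
9,0.285499999999999
10,0.256799999999999
11,0.233099999999999
12,0.218399999999999
13,0.201199999999999
14,0.186399999999999
15,0.1743
16,0.1632
17,0.1542
18,0.144899999999999
19,0.135
20,0.1289
21,0.1209
22,0.1158
23,0.1099
24,0.1045
25,0.0996999999999996
26,0.0959999999999996
27,0.0932999999999996
28,0.0893999999999996
29,0.0864999999999996
30,0.0825999999999996
31,0.0801999999999996
32,0.0776999999999996
33,0.0743999999999997
34,0.0721999999999997
35,0.0696999999999997
36,0.0677999999999997
37,0.0661999999999997
38,0.0641999999999997
39,0.0623999999999997
40,0.0611999999999997
41,0.0595999999999998
42,0.0576999999999998
43,0.0564999999999998
44,0.0550999999999998
45,0.0538999999999998
46,0.0528999999999998
47,0.0515999999999998
48,0.0502999999999998
49,0.0495999999999998
50,0.0487999999999998
51,0.0477999999999998
52,0.0472999999999998
53,0.0460999999999998
54,0.0455999999999998
55,0.0449999999999998
56,0.0443999999999998
57,0.0436999999999998
58,0.0430999999999998
59,0.0425999999999998
60,0.0418999999999998
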