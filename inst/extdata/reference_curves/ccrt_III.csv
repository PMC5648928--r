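month,survival_fraction
1,0.9084
2,0.9076
3,0.906
4,0.9045
5,0.9036
6,0.899
7,0.878200000000001
8,0.8407
9,0.7924
10,0.735000000000001
11,0.684200000000001
12,0.636200000000001
13,0.5931
14,0.553400000000001
15,0.5187
16,0.4865
17,0.462
18,0.4371
19,0.4156
20,0.397199999999999
21,0.380199999999999
22,0.364899999999999
23,0.350399999999999
24,0.336099999999999
25,0.322799999999999
26,0.312599999999999
27,0.302499999999999
28,0.293099999999999
29,0.284799999999999
30,0.276099999999999
31,0.267699999999999
32,0.261799999999999
33,0.253299999999999
34,0.248099999999999
35,0.241799999999999
36,0.236599999999999
37,0.231399999999999
38,0.227099999999999
39,0.221599999999999
40,0.216699999999999
41,0.212899999999999
42,0.208999999999999
43,0.203399999999999
44,0.200099999999999
45,0.197399999999999
46,0.194299999999999
47,0.190599999999999
48,0.1881
49,0.185099999999999
50,0.181799999999999
51,0.1787
52,0.1766
53,0.1746
54,0.1719
55,0.169
56,0.167
57,0.1648
58,0.163
59,0.1617
60,0.1596
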