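month,survival_fraction
1,0.706000000000001
2,0.4972
3,0.367699999999999
4,0.288599999999999
5,0.235799999999999
6,0.201499999999999
7,0.1753
8,0.1545
9,0.139699999999999
10,0.1256
11,0.1153
12,0.1066
13,0.0971999999999996
14,0.0913999999999996
15,0.0856999999999996
16,0.0806999999999996
17,0.0764999999999996
18,0.0730999999999997
19,0.0692999999999997
20,0.0659999999999997
21,0.0629999999999997
22,0.0598999999999998
23,0.0565999999999998
24,0.0537999999999998
25,0.0514999999999998
26,0.0496999999999998
27,0.0481999999999998
28,0.0456999999999998
29,0.0440999999999998
30,0.0424999999999998
31,0.0410999999999998
32,0.0404999999999998
33,0.0391999999999998
34,0.0379999999999999
35,0.0367999999999999
36,0.0357999999999999
37,0.0351999999999999
38,0.0342999999999999
39,0.0336999999999999
40,0.0328999999999999
41,0.0319999999999999
42,0.0312999999999999
43,0.0299999999999999
44,0.0286999999999999
45,0.0277999999999999
46,0.0269999999999999
47,0.0263999999999999
48,0.0260999999999999
49,0.0254999999999999
50,0.0250999999999999
51,0.0249999999999999
52,0.0246999999999999
53,0.0240999999999999
54,0.0234999999999999
55,0.0232999999999999
56,0.0228999999999999
57,0.0227999999999999
58,0.0222999999999999
59,0.0221999999999999
60,0.0218999999999999
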