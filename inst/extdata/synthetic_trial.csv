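id,time,status,x
1,0.64281,1,1
2,0.15543,1,1
3,0.51453,0,0
4,1,0,0
5,0.42731,0,1
6,0.06276,1,0
7,0.48686,2,0
8,0.67992,2,1
9,0.04231,1,0
10,0.58001,2,1
11,0.49845,2,0
12,0.3929,0,1
13,0.0366,1,0
14,0.10771,1,1
15,1,0,0
16,0.00421,1,0
17,0.18929,1,1
18,0.70976,2,0
19,0.08317,0,0
20,0.41014,2,0
21,1,0,0
22,0.33509,2,0
23,0.69749,2,0
24,1,0,0
25,1,0,0
26,0.07766,1,0
27,0.22126,1,0
28,1,0,0
29,0.57087,0,0
30,0.06364,1,1
31,0.19767,2,1
32,0.04973,1,0
33,0.33277,0,1
34,0.76673,1,0
35,1,0,1
36,1,0,0
37,0.45517,2,0
38,1,0,0
39,1,0,1
40,0.02726,1,0
41,0.13231,2,0
42,0.77046,1,1
43,1,0,0
44,0.1197,2,0
45,0.13232,2,0
46,0.47572,1,0
47,0.06799,2,1
48,0.5949,1,0
49,0.71186,1,1
50,0.10374,2,0
51,0.68454,0,1
52,1,0,1
53,0.74912,1,1
54,0.49403,0,1
55,0.27846,1,1
56,0.92442,1,1
57,1,0,1
58,1,0,0
59,1,0,1
60,0.7442,1,0
61,0.0254,1,0
62,0.34731,2,1
63,1,0,1
64,0.99347,1,0
65,0.12348,0,0
66,0.30406,1,0
67,1,0,1
68,0.15441,1,0
69,0.03824,1,1
70,0.58093,1,1
71,0.06085,0,1
72,0.1053,2,0
73,0.2037,2,1
74,1,0,1
75,0.37391,1,0
76,0.38449,0,1
77,0.16709,2,1
78,0.87688,2,1
79,1,0,0
80,0.2366,1,1
81,0.51129,0,0
82,0.66549,0,1
83,0.40889,2,1
84,1,0,1
85,0.52747,1,0
86,1,0,1
87,0.15749,1,1
88,0.45469,0,1
89,1,0,0
90,0.07637,0,0
91,1,0,1
92,0.17588,1,1
93,0.06696,1,1
94,0.0768,2,0
95,1,0,0
96,0.42636,0,0
97,0.14238,2,1
98,0.15278,1,0
99,0.17444,2,1
100,0.42612,2,0
101,0.03803,0,0
102,1,0,1
103,0.12369,1,0
104,1,0,0
105,0.45244,2,0
106,1,0,0
107,1,0,1
108,0.15527,2,1
109,0.27253,1,0
110,0.22404,2,1
111,0.54669,1,0
112,0.25036,1,1
113,0.49301,1,0
114,0.68627,1,0
115,1,0,0
116,1,0,0
117,1,0,1
118,0.07443,1,0
119,0.15381,1,0
120,1,0,1
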