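# Synthetic approximation of the 2018 US female period life table.
# Constructed by log-linear interpolation of annual death probabilities
# through age knots chosen to match the published table; NOT a transcription.
# Summary checks at build time: e0, e40, e65 within ~0.5y of published values.
age,annual_death_prob
0,0.00519
1,0.00037
2,0.00023
3,0.00018
4,0.00014
5,0.00013
6,0.000127935
7,0.000125904
8,0.000123904
9,0.000121936
10,0.00012
11,0.000134164
12,0.00015
13,0.000182466
14,0.000221959
15,0.00027
16,0.000305209
17,0.000345009
18,0.00039
19,0.000414246
20,0.00044
21,0.000469708
22,0.000501422
23,0.000535277
24,0.000571419
25,0.00061
26,0.000645596
27,0.000683269
28,0.000723141
29,0.000765339
30,0.00081
31,0.00085477
32,0.000902014
33,0.00095187
34,0.00100448
35,0.00106
36,0.00111417
37,0.00117111
38,0.00123096
39,0.00129387
40,0.00136
41,0.00146588
42,0.00158
43,0.00171483
44,0.00186117
45,0.00202
46,0.00219495
47,0.00238506
48,0.00259163
49,0.0028161
50,0.00306
51,0.00331704
52,0.00359566
53,0.0038977
54,0.0042251
55,0.00458
56,0.00493317
57,0.00531357
58,0.00572331
59,0.00616464
60,0.00664
61,0.007198
62,0.00780289
63,0.00845861
64,0.00916944
65,0.00994
66,0.0108915
67,0.0119342
68,0.0130766
69,0.0143284
70,0.0157
71,0.0171614
72,0.0187589
73,0.020505
74,0.0224137
75,0.0245
76,0.0271575
77,0.0301032
78,0.0333685
79,0.036988
80,0.041
81,0.0460142
82,0.0516416
83,0.0579572
84,0.0650452
85,0.073
86,0.0821813
87,0.0925174
88,0.104153
89,0.117253
90,0.132
91,0.147247
92,0.164255
93,0.183227
94,0.204391
95,0.228
96,0.24697
97,0.267518
98,0.289775
99,0.313885
100,0.34
101,0.362746
102,0.387014
103,0.412905
104,0.440529
105,0.47
106,0.493524
107,0.518226
108,0.544164
109,0.5714
110,0.6
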