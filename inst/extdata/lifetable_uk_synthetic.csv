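age,qx
0,0.000232
1,0.000233
2,0.000234
3,0.000236
4,0.000238
5,0.000240
6,0.000242
7,0.000244
8,0.000247
9,0.000250
10,0.000253
11,0.000257
12,0.000261
13,0.000265
14,0.000270
15,0.000276
16,0.000282
17,0.000289
18,0.000297
19,0.000305
20,0.000315
21,0.000325
22,0.000337
23,0.000350
24,0.000364
25,0.000380
26,0.000398
27,0.000417
28,0.000439
29,0.000464
30,0.000491
31,0.000520
32,0.000554
33,0.000591
34,0.000632
35,0.000677
36,0.000728
37,0.000784
38,0.000847
39,0.000916
40,0.000993
41,0.001078
42,0.001173
43,0.001279
44,0.001396
45,0.001526
46,0.001671
47,0.001831
48,0.002010
49,0.002207
50,0.002427
51,0.002671
52,0.002942
53,0.003243
54,0.003577
55,0.003948
56,0.004360
57,0.004818
58,0.005325
59,0.005889
60,0.006515
61,0.007209
62,0.007980
63,0.008835
64,0.009785
65,0.010838
66,0.012006
67,0.013303
68,0.014741
69,0.016335
70,0.018103
71,0.020063
72,0.022236
73,0.024643
74,0.027310
75,0.030264
76,0.033534
77,0.037153
78,0.041158
79,0.045585
80,0.050480
81,0.055886
82,0.061855
83,0.068441
84,0.075701
85,0.083699
86,0.092502
87,0.102180
88,0.112808
89,0.124466
90,0.137235
91,0.151199
92,0.166444
93,0.183057
94,0.201121
95,0.220717
96,0.241920
97,0.264794
98,0.289393
99,0.315751
100,0.343883
101,0.373776
102,0.405385
103,0.438626
104,0.473374
105,0.509454
106,0.546637
107,0.584643
108,0.623134
109,0.661719
110,1.000000
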