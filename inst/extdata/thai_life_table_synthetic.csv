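age,qx
40,0.00349388
41,0.00371217
42,0.00394952
43,0.00420761
44,0.00448825
45,0.00479338
46,0.00512514
47,0.00548586
48,0.00587803
49,0.00630439
50,0.00676791
51,0.0072718
52,0.00781956
53,0.00841497
54,0.00906215
55,0.00976556
56,0.01053
57,0.0113608
58,0.0122637
59,0.0132447
60,0.0143105
61,0.0154684
62,0.0167263
63,0.0180926
64,0.0195764
65,0.0211877
66,0.0229373
67,0.0248365
68,0.026898
69,0.0291352
70,0.0315627
71,0.0341959
72,0.0370517
73,0.0401483
74,0.0435048
75,0.0471422
76,0.0510826
77,0.0553498
78,0.0599692
79,0.0649677
80,0.070374
81,0.0762187
82,0.0825337
83,0.0893532
84,0.0967127
85,0.10465
86,0.113203
87,0.122413
88,0.132321
89,0.142971
90,0.154406
91,0.166669
92,0.179806
93,0.193858
94,0.208869
95,0.224878
96,0.241922
97,0.260035
98,0.279244
99,0.29957
100,0.321028
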