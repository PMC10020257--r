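age,incidence,mortality
20,8.09379e-05,0.000206454
21,9.14956e-05,0.000225445
22,0.000103398,0.000246183
23,0.000116808,0.000268829
24,0.000131905,0.000293558
25,0.000148887,0.000320562
26,0.000167971,0.00035005
27,0.000189395,0.000382251
28,0.000213416,0.000417413
29,0.000240315,0.00045581
30,0.00027039,0.000497739
31,0.00030396,0.000543526
32,0.000341362,0.000593524
33,0.000382946,0.000648121
34,0.000429073,0.00070774
35,0.000480108,0.000772844
36,0.000536413,0.000843936
37,0.000598339,0.000921568
38,0.000666212,0.00100634
39,0.000740324,0.00109891
40,0.000820915,0.0012
41,0.00090816,0.00131039
42,0.00100215,0.00143093
43,0.00110288,0.00156255
44,0.00121024,0.00170629
45,0.00132397,0.00186325
46,0.0014437,0.00203465
47,0.0015689,0.00222181
48,0.00169893,0.00242619
49,0.001833,0.00264937
50,0.00197021,0.00289308
51,0.00210956,0.00315921
52,0.00225,0.00344982
53,0.00239044,0.00376716
54,0.00252979,0.00411369
55,0.002667,0.00449211
56,0.00280107,0.00490533
57,0.0029311,0.00535656
58,0.0030563,0.0058493
59,0.00317603,0.00638736
60,0.00328976,0.00697492
61,0.00339712,0.00761654
62,0.00349785,0.00831717
63,0.00359184,0.00908225
64,0.00367909,0.00991771
65,0.00375968,0.01083
66,0.00383379,0.0118262
67,0.00390166,0.0129141
68,0.00396359,0.0141021
69,0.00401989,0.0153993
70,0.00407093,0.0168158
71,0.00411705,0.0183627
72,0.00415864,0.0200519
73,0.00419604,0.0218964
74,0.00422961,0.0239106
75,0.00425969,0.0261101
76,0.00428658,0.0285119
77,0.00431061,0.0311347
78,0.00433203,0.0339987
79,0.00435111,0.0371261
80,0.00436809,0.0405413
81,0.00438319,0.0442706
82,0.0043966,0.048343
83,0.0044085,0.05279
84,0.00441906,0.057646
85,0.00442842,0.0629488
86,0.00443671,0.0687393
87,0.00444406,0.0750625
88,0.00445056,0.0819674
89,0.00445631,0.0895074
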