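molecule_id,is_test,b3lyp_631gd,b3lyp_sto3g,dft_rbfnn_631gd,dft_rbfnn_sto3g,dft_sofm_rbfnn_631gd,dft_sofm_rbfnn_sto3g
1,FALSE,-17.17,-6.89,-0.12,-1.84,-0.04,-1.18
2,FALSE,-7.88,2.66,0.46,0.12,0.38,0.22
3,FALSE,-9.31,0.85,-0.48,-0.65,-0.38,-0.58
4,FALSE,-9.29,1.27,-0.03,-0.02,-0.01,-0.01
5,FALSE,-9.77,0.14,0.00,-0.01,0.00,0.00
6,TRUE,-9.13,1.04,-0.40,-0.53,-0.34,-0.46
7,FALSE,-9.01,1.11,0.05,-0.01,0.03,0.01
8,FALSE,-12.53,0.28,-0.03,0.00,-0.01,0.00
9,FALSE,-13.13,-3.06,0.00,0.00,0.00,0.00
10,FALSE,-10.9,-0.51,-0.01,-0.01,0.00,0.00
11,FALSE,2.16,12.31,0.07,0.02,0.04,0.01
12,FALSE,2.70,13.23,0.58,0.81,0.55,0.68
13,FALSE,1.72,12.17,-0.34,0.42,-0.34,0.23
14,FALSE,-0.39,10.26,-0.10,0.03,-0.06,0.01
15,FALSE,-1.56,10.1,0.00,0.01,0.00,0.01
16,FALSE,1.69,11.63,0.00,0.01,0.00,0.00
17,FALSE,2.00,12.39,-0.20,0.25,-0.23,0.13
18,FALSE,-8.37,2.73,-0.16,0.05,-0.06,0.03
19,FALSE,-7.30,4.12,-0.28,-0.02,-0.21,-0.01
20,TRUE,-6.93,4.16,-0.22,-0.47,-0.21,-0.41
21,FALSE,-7.68,3.96,0.29,0.01,0.27,0.00
22,FALSE,-10.58,0.56,0.00,0.00,0.00,0.00
23,FALSE,-2.11,8.33,0.01,-0.93,0.06,-0.75
24,FALSE,3.45,12.33,0.35,0.67,0.19,0.45
25,FALSE,-8.07,3.05,-0.53,-0.21,-0.51,-0.18
26,FALSE,-7.90,3.23,0.28,0.18,0.29,0.17
27,TRUE,-8.60,2.58,-0.42,-0.01,-0.38,-0.01
28,FALSE,-8.22,4.07,0.01,0.00,0.00,0.00
29,FALSE,-4.97,6.77,0.00,0.00,0.00,0.00
30,FALSE,1.87,-11.2,0.00,0.02,0.00,0.01
31,TRUE,1.97,-11.27,-0.05,0.00,-0.04,0.00
32,FALSE,0.33,-12.53,-0.01,-0.03,0.00,-0.02
33,TRUE,1.91,-6.79,0.04,-0.03,0.03,-0.03
34,FALSE,0.74,-11.6,0.00,0.00,0.00,0.00
35,FALSE,1.92,-10.83,0.18,0.01,0.15,0.01
36,FALSE,0.62,-14,-0.18,0.00,-0.15,0.00
37,FALSE,1.16,10.52,0.00,0.00,0.00,0.00
38,FALSE,0.76,11.2,0.14,0.12,0.10,0.10
39,FALSE,0.29,11.06,-0.05,-0.09,-0.07,-0.08
40,FALSE,-0.36,10.68,-0.06,-0.39,-0.05,-0.36
41,FALSE,-0.41,11.52,0.00,0.00,0.00,0.00
42,FALSE,-0.04,11.72,0.02,0.40,0.01,0.37
43,FALSE,-0.26,10.28,0.04,-0.05,0.04,-0.03
44,TRUE,-1.14,11.08,1.01,0.95,0.92,0.84
45,FALSE,-0.97,9.89,0.00,0.00,0.00,0.00
46,FALSE,0.03,12.03,0.00,0.00,0.00,0.00
47,FALSE,0.87,10.84,0.02,0.04,0.01,0.02
48,FALSE,-1.67,8.65,0.00,0.00,0.00,0.00
49,FALSE,-3.41,8.59,-0.01,-0.03,0.00,-0.02
50,FALSE,7.47,-0.71,-0.01,0.01,0.01,0.01
51,FALSE,5.60,-0.55,0.00,0.00,0.00,0.00
52,FALSE,7.03,-1.38,0.03,0.00,0.01,0.00
53,FALSE,6.33,-2.14,-0.01,-0.01,-0.01,-0.01
54,FALSE,-2.62,15.71,0.00,0.00,0.00,0.00
55,FALSE,-2.88,15.23,0.12,0.28,0.08,0.25
56,FALSE,-3.88,14.1,-0.12,-0.28,-0.08,-0.25
57,FALSE,-3.89,13.76,0.00,-0.01,0.00,-0.01
58,TRUE,-7.57,9.35,0.00,0.00,0.00,0.00
59,FALSE,-4.88,12.76,1.26,1.19,1.20,1.14
60,FALSE,-7.33,9.84,-1.20,-1.15,-1.16,-1.12
61,FALSE,-6.90,10.9,0.17,0.26,0.20,0.28
62,FALSE,6.39,18.5,0.00,0.00,0.00,0.00
63,FALSE,4.12,17.94,0.00,0.38,0.00,0.35
64,FALSE,-9.96,16.41,0.00,-0.37,0.00,-0.34
65,FALSE,4.19,15.06,0.00,-0.01,0.00,-0.01
66,FALSE,0.55,14.42,0.00,0.00,0.00,0.00
67,FALSE,-3.51,19.3,-0.60,-0.52,-0.47,-0.43
68,FALSE,-2.46,21.15,-0.93,-0.93,-0.85,-0.90
69,FALSE,0.27,22.96,0.51,0.57,0.44,0.54
70,FALSE,0.05,22.7,0.07,0.50,0.04,0.47
71,TRUE,2.43,22.6,0.19,0.18,0.16,0.14
72,FALSE,0.20,19.63,0.01,0.00,0.00,0.00
73,FALSE,-0.88,20.53,-0.16,-0.52,-0.09,-0.48
74,FALSE,7.91,19.5,0.02,0.03,0.01,0.02
75,FALSE,-0.36,22.56,0.38,0.39,0.39,0.40
76,FALSE,2.96,21.38,0.00,0.00,0.00,0.00
77,FALSE,1.69,22.06,0.83,0.53,0.61,0.43
78,FALSE,2.77,21.23,0.00,0.01,0.00,0.01
79,FALSE,2.52,20.27,0.21,0.00,0.13,0.00
80,FALSE,0.84,19.65,0.01,-0.01,0.00,-0.01
81,FALSE,1.17,21.22,0.00,0.00,0.00,0.00
82,FALSE,0.68,20.49,-0.21,0.00,-0.13,0.00
83,TRUE,-2.03,16.73,-0.27,-0.57,-0.26,-0.56
84,TRUE,-0.24,18.15,0.27,0.57,0.26,0.56
85,TRUE,-7.63,2.33,-0.04,0.02,-0.03,0.02
86,FALSE,-4.58,6.59,0.00,0.00,0.00,0.00
87,FALSE,-7.16,5.16,0.48,0.16,0.36,0.12
88,FALSE,-8.00,2.5,0.02,0.10,0.01,0.07
89,FALSE,-3.70,11.26,0.00,0.00,0.00,0.00
90,FALSE,-10.85,0.62,-0.49,-0.26,-0.37,-0.18
91,TRUE,-8.77,5.98,-0.16,-0.17,-0.13,-0.13
92,FALSE,-8.61,1.34,0.00,0.00,0.00,0.00
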