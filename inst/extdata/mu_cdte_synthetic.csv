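energy_keV,mu_per_mm
15,2.068432e+01
16,1.705928e+01
17,1.423740e+01
18,1.200801e+01
19,1.022341e+01
20,8.777960e+00
21,7.594770e+00
22,6.616946e+00
23,5.801787e+00
24,5.116818e+00
25,4.537044e+00
26,4.043015e+00
27,1.645895e+01
28,1.476658e+01
29,1.329960e+01
30,1.202170e+01
31,1.090337e+01
32,1.840409e+01
33,1.678858e+01
34,1.535754e+01
35,1.408536e+01
36,1.295061e+01
37,1.193520e+01
38,1.102385e+01
39,1.020356e+01
40,9.463231e+00
41,8.793353e+00
42,8.185738e+00
43,7.633315e+00
44,7.129954e+00
45,6.670325e+00
46,6.249779e+00
47,5.864246e+00
48,5.510155e+00
49,5.184364e+00
50,4.884100e+00
51,4.606909e+00
52,4.350615e+00
53,4.113284e+00
54,3.893193e+00
55,3.688804e+00
56,3.498740e+00
57,3.321766e+00
58,3.156773e+00
59,3.002764e+00
60,2.858838e+00
61,2.724183e+00
62,2.598063e+00
63,2.479812e+00
64,2.368825e+00
65,2.264551e+00
66,2.166490e+00
67,2.074185e+00
68,1.987220e+00
69,1.905212e+00
70,1.827814e+00
71,1.754705e+00
72,1.685592e+00
73,1.620204e+00
74,1.558293e+00
75,1.499632e+00
76,1.444008e+00
77,1.391228e+00
78,1.341111e+00
79,1.293491e+00
80,1.248214e+00
81,1.205138e+00
82,1.164129e+00
83,1.125065e+00
84,1.087832e+00
85,1.052323e+00
86,1.018439e+00
87,9.860877e-01
88,9.551834e-01
89,9.256456e-01
90,8.973994e-01
91,8.703744e-01
92,8.445053e-01
93,8.197305e-01
94,7.959925e-01
95,7.732374e-01
96,7.514145e-01
97,7.304764e-01
98,7.103784e-01
99,6.910786e-01
100,6.725374e-01
101,6.547178e-01
102,6.375848e-01
103,6.211054e-01
104,6.052485e-01
105,5.899848e-01
106,5.752866e-01
107,5.611278e-01
108,5.474837e-01
109,5.343309e-01
110,5.216474e-01
111,5.094121e-01
112,4.976054e-01
113,4.862085e-01
114,4.752035e-01
115,4.645737e-01
116,4.543030e-01
117,4.443762e-01
118,4.347789e-01
119,4.254974e-01
120,4.165188e-01
121,4.078305e-01
122,3.994209e-01
123,3.912787e-01
124,3.833933e-01
125,3.757545e-01
126,3.683526e-01
127,3.611785e-01
128,3.542232e-01
129,3.474784e-01
130,3.409360e-01
131,3.345886e-01
132,3.284286e-01
133,3.224493e-01
134,3.166438e-01
135,3.110059e-01
136,3.055294e-01
137,3.002085e-01
138,2.950377e-01
139,2.900116e-01
140,2.851250e-01
141,2.803731e-01
142,2.757513e-01
143,2.712549e-01
144,2.668798e-01
145,2.626217e-01
146,2.584767e-01
147,2.544410e-01
148,2.505110e-01
149,2.466831e-01
150,2.429540e-01
151,2.393205e-01
152,2.357794e-01
153,2.323277e-01
154,2.289627e-01
155,2.256814e-01
156,2.224814e-01
157,2.193599e-01
158,2.163146e-01
159,2.133432e-01
160,2.104432e-01
161,2.076126e-01
162,2.048492e-01
163,2.021509e-01
164,1.995159e-01
165,1.969422e-01
166,1.944280e-01
167,1.919716e-01
168,1.895712e-01
169,1.872252e-01
170,1.849321e-01
171,1.826902e-01
172,1.804982e-01
173,1.783547e-01
174,1.762581e-01
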