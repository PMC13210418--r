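energy_keV,relative_fluence
15,5.855031e-06
16,2.775437e-05
17,9.395917e-05
18,2.473110e-04
19,5.376096e-04
20,1.008344e-03
21,1.667362e-03
22,2.524643e-03
23,3.562086e-03
24,4.746671e-03
25,6.036852e-03
26,7.388502e-03
27,8.759483e-03
28,1.011261e-02
29,1.141717e-02
30,1.264937e-02
31,1.370280e-02
32,1.466017e-02
33,1.551707e-02
34,1.627235e-02
35,1.692744e-02
36,1.748562e-02
37,1.795149e-02
38,1.833052e-02
39,1.862870e-02
40,1.885224e-02
41,1.894616e-02
42,1.898510e-02
43,1.897453e-02
44,1.891959e-02
45,1.882504e-02
46,1.869531e-02
47,1.853445e-02
48,1.834616e-02
49,1.813383e-02
50,1.790053e-02
51,1.761925e-02
52,1.732580e-02
53,1.702215e-02
54,1.671003e-02
55,1.639100e-02
56,1.606644e-02
57,1.573759e-02
58,4.145153e-02
59,6.262290e-02
60,1.473555e-02
61,1.438289e-02
62,1.403204e-02
63,1.368344e-02
64,1.333748e-02
65,1.299449e-02
66,1.265474e-02
67,2.931891e-02
68,1.198589e-02
69,1.604739e-02
70,7.933899e-03
71,7.810531e-03
72,7.680586e-03
73,7.544693e-03
74,7.403441e-03
75,7.257381e-03
76,7.107025e-03
77,6.952853e-03
78,6.795308e-03
79,6.634803e-03
80,6.471722e-03
81,6.301590e-03
82,6.130059e-03
83,5.957403e-03
84,5.783874e-03
85,5.609704e-03
86,5.435106e-03
87,5.260275e-03
88,5.085392e-03
89,4.910619e-03
90,4.736106e-03
91,4.561992e-03
92,4.388399e-03
93,4.215443e-03
94,4.043226e-03
95,3.871841e-03
96,3.701374e-03
97,3.531900e-03
98,3.363488e-03
99,3.196201e-03
100,3.030093e-03
101,2.864913e-03
102,2.701035e-03
103,2.538498e-03
104,2.377337e-03
105,2.217581e-03
106,2.059258e-03
107,1.902388e-03
108,1.746990e-03
109,1.593079e-03
110,1.440667e-03
111,1.289764e-03
112,1.140377e-03
113,9.925097e-04
114,8.461655e-04
115,7.013447e-04
116,5.580463e-04
117,4.162674e-04
118,2.760039e-04
119,1.372504e-04
120,0.000000e+00
121,0.000000e+00
122,0.000000e+00
123,0.000000e+00
124,0.000000e+00
125,0.000000e+00
126,0.000000e+00
127,0.000000e+00
128,0.000000e+00
129,0.000000e+00
130,0.000000e+00
131,0.000000e+00
132,0.000000e+00
133,0.000000e+00
134,0.000000e+00
135,0.000000e+00
136,0.000000e+00
137,0.000000e+00
138,0.000000e+00
139,0.000000e+00
140,0.000000e+00
141,0.000000e+00
142,0.000000e+00
143,0.000000e+00
144,0.000000e+00
145,0.000000e+00
146,0.000000e+00
147,0.000000e+00
148,0.000000e+00
149,0.000000e+00
150,0.000000e+00
151,0.000000e+00
152,0.000000e+00
153,0.000000e+00
154,0.000000e+00
155,0.000000e+00
156,0.000000e+00
157,0.000000e+00
158,0.000000e+00
159,0.000000e+00
160,0.000000e+00
161,0.000000e+00
162,0.000000e+00
163,0.000000e+00
164,0.000000e+00
165,0.000000e+00
166,0.000000e+00
167,0.000000e+00
168,0.000000e+00
169,0.000000e+00
170,0.000000e+00
171,0.000000e+00
172,0.000000e+00
173,0.000000e+00
174,0.000000e+00
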