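energy_MeV,bragg_mm,n13_mm,offset_mm
45,17,15,2
50,21,19,2
55,25,23,2
60,29.5,28,1.5
65,34,32,2
70,39,37,2
75,44,42,2
80,50,48,2
85,56,54,2
90,62,60,2
95,68,66,2
100,75,73,2
105,81.5,80,1.5
110,88.5,87,1.5
115,96,94,2
120,103.5,102,1.5
125,110.5,109,1.5
130,119,117,2
135,127,126,1
140,136,134,2
145,145,143,2
150,153,152,1
155,163,161,2
160,172,170,2
165,181,180,1
170,191,189,2
175,201,199,2
180,211,209,2
185,221,219,2
190,232,230,2
195,242,241,1
200,253,251,2
205,264,262,2
210,275,274,1
215,287,285,2
220,298,296,2
225,310,308,2
230,322,320,2
235,334,332,2
240,345,344,1
245,358,356,2
250,371,369,2
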