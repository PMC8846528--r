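energy_MeV,mass_stopping_MeV_cm2_g
0.5,428.16
0.75,328.7955
1,269.7052
1.25,230.1288
1.5,201.5725
1.75,179.8909
2,162.8076
2.5,137.4907
3,119.529
3.5,106.0586
4,95.546
4.5,87.0914
5,80.1305
5.5,74.2903
6,69.3138
6.5,65.018
7,61.2689
7.5,57.9657
8,55.0314
8.5,52.406
9,50.042
9.5,47.9011
10,45.9525
11,42.5348
12,39.6323
13,37.1344
14,34.9602
15,33.0492
16,31.3554
17,29.843
18,28.4836
19,27.2547
20,26.138
21,25.1185
22,24.1836
23,23.3232
24,22.5283
25,21.7918
26,21.1072
27,20.4691
28,19.8729
29,19.3144
30,18.7902
32.5,17.6098
35,16.5852
37.5,15.687
40,14.8928
42.5,14.1852
45,13.5506
47.5,12.978
50,12.4586
52.5,11.9852
55,11.5519
57.5,11.1537
60,10.7865
62.5,10.4467
65,10.1312
67.5,9.8377
70,9.5637
72.5,9.3074
75,9.0671
77.5,8.8414
80,8.6289
82.5,8.4285
85,8.2391
87.5,8.0599
90,7.8901
92.5,7.729
95,7.5758
97.5,7.43
100,7.2911
105,7.032
110,6.7953
115,6.578
120,6.378
125,6.1931
130,6.0217
135,5.8625
140,5.714
145,5.5754
150,5.4456
155,5.3238
160,5.2093
165,5.1014
170,4.9997
175,4.9035
180,4.8125
185,4.7263
190,4.6444
195,4.5665
200,4.4925
205,4.4219
210,4.3547
215,4.2904
220,4.229
225,4.1703
230,4.114
235,4.0601
240,4.0084
245,3.9587
250,3.911
255,3.8652
260,3.8211
265,3.7786
270,3.7376
275,3.6982
280,3.6601
285,3.6234
290,3.5879
295,3.5536
300,3.5205
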