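energy_MeV,sigma_mb
0,0
20.61,0
25,40
30,75
35,88
40,95
45,93
50,90
60,85
80,75
100,70
150,60
200,54
250,50
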