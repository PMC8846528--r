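energy_MeV,sigma_mb
0,0
16.79,0
20,30
25,65
30,72
35,68
40,60
50,50
60,45
80,41
100,39
150,37
250,35
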