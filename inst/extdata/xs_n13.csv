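energy_MeV,sigma_mb
0,0
5.66,0
6.5,2
8,9
10,16
13,20
16,16
20,11
25,8
30,6.5
37.5,5
60,5
120,5
250,5
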