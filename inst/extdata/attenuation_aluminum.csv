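energy_keV,mu_per_cm
10,70.79
15,21.47
20,9.29
30,3.04
40,1.53
50,0.994
60,0.750
80,0.545
100,0.460
150,0.372
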