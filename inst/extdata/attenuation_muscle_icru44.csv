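energy_keV,mu_per_cm
10,5.624
15,1.778
20,0.862
30,0.394
40,0.282
50,0.238
60,0.215
80,0.191
100,0.178
150,0.157
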