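energy_keV,mu_per_cm
10,54.74
15,17.34
20,7.68
30,2.56
40,1.28
50,0.815
60,0.604
80,0.428
100,0.356
150,0.284
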