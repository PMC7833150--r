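# Fluence-to-dose conversion coefficients for photons, transcribed from the
# ICRP-74 style tables of the joint ICRP/ICRU task group.
#   hstar10 : ambient dose equivalent H*(10) per fluence, pSv cm2
#   kerma   : air kerma free-in-air per fluence, pGy cm2
# Log-log interpolation between nodes is intended.
# columns: quantity  energy_keV  coefficient
hstar10 50 0.54
hstar10 60 0.51
hstar10 80 0.53
hstar10 100 0.61
hstar10 150 0.89
hstar10 200 1.20
hstar10 300 1.80
hstar10 400 2.38
hstar10 500 2.93
hstar10 600 3.44
hstar10 800 4.38
hstar10 1000 5.20
hstar10 1500 6.90
hstar10 2000 8.60
hstar10 3000 11.10
kerma 50 0.323
kerma 60 0.289
kerma 80 0.307
kerma 100 0.371
kerma 150 0.599
kerma 200 0.856
kerma 300 1.38
kerma 400 1.89
kerma 500 2.38
kerma 600 2.84
kerma 800 3.69
kerma 1000 4.47
kerma 1500 6.12
kerma 2000 7.51
kerma 3000 9.89
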