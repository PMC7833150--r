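# Berger-form buildup-factor coefficients, B(mu*r) = 1 + a * mu*r * exp(b * mu*r),
# fitted to infinite-medium dose buildup data for point isotropic sources
# (water/air-equivalent media; concrete and soil fits carry slightly smaller
# linear coefficients).  a and b are interpolated log-log in energy.
# columns: material  energy_keV  a  b
air 50 1.60 0.180
air 100 1.90 0.160
air 200 1.70 0.120
air 300 1.50 0.100
air 500 1.25 0.080
air 662 1.10 0.070
air 1000 0.95 0.055
air 1500 0.85 0.045
air 2000 0.78 0.040
air 3000 0.70 0.035
concrete 50 1.44 0.180
concrete 100 1.71 0.160
concrete 200 1.53 0.120
concrete 300 1.35 0.100
concrete 500 1.13 0.080
concrete 662 0.99 0.070
concrete 1000 0.86 0.055
concrete 1500 0.77 0.045
concrete 2000 0.70 0.040
concrete 3000 0.63 0.035
soil 50 1.44 0.180
soil 100 1.71 0.160
soil 200 1.53 0.120
soil 300 1.35 0.100
soil 500 1.13 0.080
soil 662 0.99 0.070
soil 1000 0.86 0.055
soil 1500 0.77 0.045
soil 2000 0.70 0.040
soil 3000 0.63 0.035
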