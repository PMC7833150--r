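# Principal gamma-ray emission lines per decay, transcribed from an
# ENSDF-style decay-data compilation.  Intensities are photons per decay.
# Lines below 50 keV or with intensity < 1% of the strongest line of the
# nuclide are omitted.  137Cs includes the 661.66 keV line of its 137mBa
# progeny in radioactive equilibrium.
# columns: nuclide  energy_keV  intensity
85Kr 514.00 0.00434
132Te 228.16 0.880
131I 80.19 0.0262
131I 284.31 0.0614
131I 364.49 0.8150
131I 636.99 0.0718
131I 722.91 0.0177
132I 522.65 0.1610
132I 630.19 0.1370
132I 667.71 0.9870
132I 772.60 0.7560
132I 954.55 0.1750
132I 1398.57 0.0701
133I 529.87 0.8700
133I 875.33 0.0451
133I 1236.44 0.0151
133Xe 81.00 0.3800
134Cs 475.37 0.0148
134Cs 563.25 0.0835
134Cs 569.33 0.1538
134Cs 604.72 0.9762
134Cs 795.86 0.8546
134Cs 801.95 0.0869
134Cs 1365.19 0.0302
136Cs 86.36 0.0518
136Cs 153.25 0.0575
136Cs 163.92 0.0339
136Cs 340.55 0.4220
136Cs 818.51 0.9970
136Cs 1048.07 0.8000
136Cs 1235.36 0.2000
137Cs 661.66 0.8510
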