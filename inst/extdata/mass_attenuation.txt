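# Photon mass attenuation coefficients (total, without coherent-scattering
# correction), transcribed from a NIST XCOM-style compilation for dry air
# (near sea level), ordinary concrete, and generic dry soil.
# Log-log interpolation between nodes is intended.
# columns: material  energy_keV  mu_over_rho_cm2_per_g
# default bulk densities used by the package:
#   air 1.205e-3 g/cm3, soil 1.6 g/cm3, concrete 2.3 g/cm3
air 50 0.2080
air 60 0.1875
air 80 0.1662
air 100 0.1541
air 150 0.1356
air 200 0.1233
air 300 0.1067
air 400 0.09549
air 500 0.08712
air 600 0.08055
air 800 0.07074
air 1000 0.06358
air 1250 0.05687
air 1500 0.05175
air 2000 0.04447
air 3000 0.03581
concrete 50 0.3300
concrete 60 0.2500
concrete 80 0.1800
concrete 100 0.1550
concrete 150 0.1310
concrete 200 0.1190
concrete 300 0.1073
concrete 400 0.0960
concrete 500 0.0876
concrete 600 0.0810
concrete 800 0.0711
concrete 1000 0.0639
concrete 1250 0.0572
concrete 1500 0.0520
concrete 2000 0.0447
concrete 3000 0.0362
soil 50 0.3200
soil 60 0.2450
soil 80 0.1780
soil 100 0.1540
soil 150 0.1305
soil 200 0.1188
soil 300 0.1070
soil 400 0.0958
soil 500 0.0874
soil 600 0.0808
soil 800 0.0710
soil 1000 0.0638
soil 1250 0.0571
soil 1500 0.0519
soil 2000 0.0446
soil 3000 0.0361
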