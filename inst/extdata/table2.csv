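extract,Gal,pCat,eCat,Van,Chl,Cum,Gen,Caff,Total
UE 30% MeOH,1.00 ± 0.00,10.09 ± 0.00,0.13 ± 0.00,0.50 ± 0.00,0.15 ± 0.00,0.03 ± 0.00,0.18 ± 0.00,0.01 ± 0.00,12.09 ± 0.00
UE 50% MeOH,1.20 ± 0.00,11.51 ± 0.02,1.19 ± 0.00,0.28 ± 0.00,0.09 ± 0.00,0.02 ± 0.00,0.20 ± 0.00,0.01 ± 0.00,14.50 ± 0.02
UE 30% EtOH,1.72 ± 0.01,13.89 ± 0.00,1.64 ± 0.00,0.44 ± 0.00,0.17 ± 0.00,0.02 ± 0.00,0.30 ± 0.02,0.06 ± 0.00,18.24 ± 0.03
UE H2O,1.12 ± 0.00,10.96 ± 0.00,0.35 ± 0.00,0.50 ± 0.00,0.04 ± 0.00,0.01 ± 0.00,0.19 ± 0.00,0.01 ± 0.00,13.18 ± 0.00
SE 30% MeOH,0.97 ± 0.00,10.80 ± 0.00,0.20 ± 0.00,0.68 ± 0.00,0.11 ± 0.00,0.04 ± 0.00,0.20 ± 0.01,0.02 ± 0.00,13.02 ± 0.01
SE 50% MeOH,1.09 ± 0.00,11.49 ± 0.01,0.09 ± 0.00,0.35 ± 0.00,0.15 ± 0.01,0.03 ± 0.00,0.20 ± 0.01,0.02 ± 0.00,13.42 ± 0.03
SE 50% EtOH,1.94 ± 0.00,14.51 ± 0.01,1.47 ± 0.00,0.37 ± 0.00,0.01 ± 0.00,0.05 ± 0.00,0.18 ± 0.00,0.07 ± 0.00,18.60 ± 0.01
SE H2O,0.93 ± 0.00,12.12 ± 0.01,0.79 ± 0.00,0.11 ± 0.00,0.21 ± 0.01,0.04 ± 0.00,0.14 ± 0.00,0.02 ± 0.00,14.36 ± 0.02
CE 50% MeOH,1.21 ± 0.00,11.70 ± 0.00,0.49 ± 0.00,0.22 ± 0.00,0.08 ± 0.00,0.02 ± 0.00,0.19 ± 0.00,0.02 ± 0.00,13.93 ± 0.00
CE 80% MeOH,1.21 ± 0.00,11.47 ± 0.00,0.51 ± 0.00,0.51 ± 0.00,0.08 ± 0.00,0.02 ± 0.00,0.23 ± 0.01,0.01 ± 0.00,14.04 ± 0.01
CE 50% EtOH,0.99 ± 0.00,11.71 ± 0.02,1.22 ± 0.00,0.35 ± 0.00,0.11 ± 0.00,0.02 ± 0.00,0.18 ± 0.00,0.02 ± 0.00,14.60 ± 0.02
CE H2O,1.16 ± 0.01,11.23 ± 0.00,0.41 ± 0.00,0.13 ± 0.00,0.04 ± 0.00,0.01 ± 0.00,0.19 ± 0.00,0.02 ± 0.00,13.19 ± 0.01
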