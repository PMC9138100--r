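extract,DPPH,ABTS,RP,BCB,AIA,AHgA
UE 30% MeOH,10.26 ± 1.15,2774.14 ± 95.91,147.03 ± 7.37,131.61 ± 0.11,17.62 ± 0.76,67.99 ± 3.82
UE 50% MeOH,11.36 ± 0.53,3809.27 ± 44.89,143.25 ± 7.37,133.21 ± 0.72,37.08 ± 1.88,56.60 ± 3.40
UE 30% EtOH,7.33 ± 0.69,3798.23 ± 14.20,191.07 ± 14.35,161.15 ± 8.47,33.64 ± 1.93,46.40 ± 6.52
UE H2O,11.40 ± 0.38,3964.30 ± 23.23,133.95 ± 14.07,123.98 ± 15.24,22.15 ± 1.43,38.82 ± 9.13
SE 30% MeOH,10.53 ± 1.16,4566.45 ± 55.75,177.23 ± 20.97,148.79 ± 12.70,12.92 ± 3.74,37.66 ± 1.01
SE 50% MeOH,7.22 ± 0.70,3560.76 ± 62.35,138.89 ± 4.20,116.38 ± 6.74,35.49 ± 2.66,42.81 ± 6.30
SE 50% EtOH,7.26 ± 0.37,4258.90 ± 36.56,278.00 ± 22.35,174.29 ± 13.64,37.64 ± 4.17,46.73 ± 1.68
SE H2O,11.13 ± 0.30,3520.42 ± 47.42,209.26 ± 7.50,164.41 ± 12.35,36.53 ± 1.91,40.42 ± 7.53
CE 50% MeOH,5.79 ± 1.92,3752.45 ± 67.91,149.96 ± 26.61,137.28 ± 4.71,42.86 ± 1.67,34.19 ± 3.33
CE 80% MeOH,6.11 ± 0.35,3652.92 ± 54.49,138.12 ± 5.19,128.01 ± 3.65,21.41 ± 0.80,49.61 ± 2.73
CE 50% EtOH,6.03 ± 1.09,4388.60 ± 66.94,147.64 ± 2.84,130.93 ± 8.45,42.68 ± 1.22,46.87 ± 2.91
CE H2O,8.58 ± 1.13,1559.99 ± 23.02,108.76 ± 2.99,113.26 ± 1.53,35.42 ± 0.32,44.20 ± 1.29
SFE EtOH 40 °C 100 bar,19.87 ± 0.49,4527.87 ± 19.39,209.53 ± 22.82,155.60 ± 0.51,17.38 ± 1.76,35.60 ± 5.45
SFE EtOH 40 °C 300 bar,19.86 ± 0.45,4889.60 ± 15.79,219.21 ± 5.85,142.15 ± 7.85,23.59 ± 3.37,88.08 ± 5.55
SFE EtOH 60 °C 100 bar,20.03 ± 0.59,5362.63 ± 15.27,221.54 ± 27.65,156.57 ± 6.61,24.51 ± 2.53,73.25 ± 7.58
SFE EtOH 60 °C 300 bar,11.51 ± 0.64,5786.35 ± 20.53,296.78 ± 15.27,193.07 ± 10.02,23.62 ± 1.41,67.79 ± 3.17
SFE PrOH 40 °C 100 bar,20.07 ± 0.58,3307.98 ± 44.58,108.50 ± 10.50,99.54 ± 9.14,1.11 ± 0.74,61.98 ± 1.11
SFE PrOH 40 °C 300 bar,20.39 ± 0.61,1654.50 ± 22.97,90.56 ± 5.07,67.06 ± 0.71,2.08 ± 0.91,67.98 ± 2.72
SFE PrOH 60 °C 100 bar,20.13 ± 0.67,2973.34 ± 62.09,109.58 ± 14.31,113.84 ± 9.82,4.07 ± 0.94,55.72 ± 4.21
SFE PrOH 60 °C 300 bar,19.82 ± 0.50,3886.27 ± 15.60,163.31 ± 17.49,145.94 ± 2.09,6.89 ± 1.63,66.42 ± 3.72
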