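extract,TPh,TBc,TBx
UE 30% MeOH,135.80,2.67 ± 0.09,2.59 ± 0.08
UE 50% MeOH,95.44,2.73 ± 0.14,2.63 ± 0.15
UE 30% EtOH,222.92,2.52 ± 0.12,2.49 ± 0.13
UE H2O,157.04,2.78 ± 0.12,3.33 ± 0.13
SE 30% MeOH,196.77,4.17 ± 0.17,3.41 ± 0.13
SE 50% MeOH,198.43,3.77 ± 0.24,3.37 ± 0.21
SE 50% EtOH,226.80,3.15 ± 0.17,2.67 ± 0.15
SE H2O,221.57,3.80 ± 0.15,2.38 ± 0.10
CE 50% MeOH,76.05,3.63 ± 0.18,3.29 ± 0.16
CE 80% MeOH,182.74,3.17 ± 0.20,2.66 ± 0.16
CE 50% EtOH,181.02,3.12 ± 0.15,3.03 ± 0.14
CE H2O,138.51,3.56 ± 0.13,3.77 ± 0.14
SFE EtOH 40 °C 100 bar,nd,nd,nd
SFE EtOH 40 °C 300 bar,nd,nd,nd
SFE EtOH 60 °C 100 bar,nd,nd,nd
SFE EtOH 60 °C 300 bar,nd,nd,nd
SFE PrOH 40 °C 100 bar,nd,nd,nd
SFE PrOH 40 °C 300 bar,nd,nd,nd
SFE PrOH 60 °C 100 bar,nd,nd,nd
SFE PrOH 60 °C 300 bar,nd,nd,nd
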