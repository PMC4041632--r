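# arsmet kinetic parameters (concentrations muM, time hours)
k1 = 1e-11
k_1 = 375
k2 = 1e-05
k_2 = 0.25
k3 = 0.001
k_3 = 0.001
k4 = 0.2772588722239781
k5 = 100
k6 = 0.1
k7 = 5
k8 = 0.1
Km = 4.6
KiA = 1.26
KiM = 40
KiA2 = 40
KiM2 = 6
Vmax = 2e-06
k9 = 9900
k10 = 1500
u_basal = 100
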