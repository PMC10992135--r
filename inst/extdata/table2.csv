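# Published APRPC photon doses (umol photons per cell) at six constant average
# irradiances (iav, umol photons m^-2 s^-1) and six induction times (hours).
# sd over n = 3 cultivations. Geometry: illuminated area 0.051 m^2, light path
# 0.025 m; the whole table is consistent with a single cell concentration of
# about 4.0058e7 cells/L.
iav,hours,aprpc,sd
100,2,0.02,0.001
100,4,0.05,0.002
100,8,0.09,0.002
100,12,0.14,0.002
100,16,0.18,0.001
100,24,0.28,0.002
200,2,0.05,0.002
200,4,0.09,0.002
200,8,0.18,0.001
200,12,0.28,0.002
200,16,0.37,0.002
200,24,0.55,0.002
400,2,0.09,0.002
400,4,0.18,0.001
400,8,0.36,0.002
400,12,0.55,0.002
400,16,0.73,0.001
400,24,1.10,0.030
800,2,0.18,0.002
800,4,0.37,0.002
800,8,0.73,0.001
800,12,1.10,0.030
800,16,1.47,0.030
800,24,2.20,0.012
1200,2,0.27,0.001
1200,4,0.55,0.002
1200,8,1.10,0.002
1200,12,1.65,0.010
1200,16,2.20,0.012
1200,24,3.30,0.014
1600,2,0.37,0.001
1600,4,0.73,0.001
1600,8,1.47,0.030
1600,12,2.20,0.012
1600,16,2.94,0.042
1600,24,4.40,0.024
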