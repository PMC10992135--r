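# Measured local light intensities in D. salina suspensions at incident flux
# 400 umol photons m^-2 s^-1, three biomass levels x three light paths.
# At 0.25 and 0.50 g/L the source reports percentage reductions of the
# incident intensity (51.8/68.60/89.2 % and 65.34/83.36/96.17 % at 0.025,
# 0.05, 0.10 m); local = 400 * (1 - reduction/100). At 1.50 g/L the local
# intensities 22.34, 5.31, 0.30 are reported directly.
biomass_g_per_L,depth_m,incident_umol_m2_s,local_umol_m2_s
0.25,0.025,400,192.8
0.25,0.05,400,125.6
0.25,0.10,400,43.2
0.50,0.025,400,138.64
0.50,0.05,400,66.56
0.50,0.10,400,15.32
1.50,0.025,400,22.34
1.50,0.05,400,5.31
1.50,0.10,400,0.30
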