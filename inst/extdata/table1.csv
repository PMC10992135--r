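# Optical coefficients of D. salina suspensions at six cellular beta-carotene
# contents (percent of dry weight). ka: Lambert-Beer mass extinction
# coefficient (m^2/g); ea, es: Cornet two-flux mass absorption and scattering
# coefficients (m^2/g). *_sd columns are standard deviations over n = 3
# cultivations.
bcar_content_pct,ka,ka_sd,ea,ea_sd,es,es_sd
0.56,0.0478,0.0142,0.0316,0.0015,0.718,0.021
0.84,0.0493,0.0132,0.0242,0.0010,0.754,0.017
1.21,0.0504,0.0175,0.0213,0.0036,0.757,0.014
1.93,0.0519,0.0216,0.0207,0.0042,0.846,0.018
2.88,0.0558,0.0224,0.0196,0.0026,0.883,0.013
4.26,0.0587,0.0144,0.0167,0.0032,0.948,0.060
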