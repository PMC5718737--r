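r_cm,g_perspex_mc,g_perspex_tld,g_water_mc
0.5,1.448,1.49,1.42
1,1.000,1.000,1.000
1.5,0.817,0.841,0.822
2,0.668,0.689,0.668
3,0.422,0.431,0.426
4,0.264,0.276,0.264
5,0.156,0.168,0.161
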