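r_cm,theta_deg,F
1.5,0,0.209
1.5,30,0.656
1.5,60,0.920
2,0,0.253
2,30,0.675
2,60,0.921
3,0,0.270
3,30,0.681
3,60,0.925
5,0,0.301
5,30,0.682
5,60,0.905
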