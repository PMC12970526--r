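mbcd_chol_um,mixture,gp_mean,gp_sd,n_vesicles
0,DOPC:DMPC,-0.38,0.07,50
10,DOPC:DMPC,-0.29,0.07,50
30,DOPC:DMPC,-0.10,0.12,50
100,DOPC:DMPC,0.09,0.09,50
0,DOPC:PC(18:0-14:0),-0.41,0.05,50
10,DOPC:PC(18:0-14:0),-0.30,0.06,50
30,DOPC:PC(18:0-14:0),-0.15,0.09,50
100,DOPC:PC(18:0-14:0),-0.02,0.09,50
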