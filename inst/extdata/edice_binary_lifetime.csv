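mbcd_chol_um,mixture,lifetime_mean_ns,lifetime_sd_ns,n_vesicles
0,DOPC:DMPC,3.05,0.10,50
10,DOPC:DMPC,3.68,0.12,50
30,DOPC:DMPC,4.43,0.18,50
100,DOPC:DMPC,4.80,0.19,50
0,DOPC:PC(18:0-14:0),2.98,0.11,50
10,DOPC:PC(18:0-14:0),3.57,0.21,50
30,DOPC:PC(18:0-14:0),4.15,0.17,50
100,DOPC:PC(18:0-14:0),4.63,0.22,50
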