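mbcd_chol_um,gp_mean,gp_sd,lifetime_mean_ns,lifetime_sd_ns,n_vesicles
0,-0.51,0.05,2.96,0.06,50
10,-0.44,0.08,3.41,0.05,50
30,-0.25,0.09,4.05,0.13,50
100,-0.10,0.11,4.37,0.20,50
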