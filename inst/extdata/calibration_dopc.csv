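chol_molpct,gp_mean,gp_sd,lifetime_mean_ns,lifetime_sd_ns,n_vesicles
0,-0.53,0.04,2.92,0.03,30
10,-0.45,0.05,3.32,0.07,30
25,-0.30,0.07,3.78,0.11,30
40,-0.09,0.09,4.50,0.16,30
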