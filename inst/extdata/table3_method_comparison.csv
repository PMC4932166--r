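method,divisions,ops_per_char,mean_time_s,sd_s,miss_rate_pct
EOG,2,7,77.0,8.7,2.06
sEMG,2,7,66.0,14.1,0.07
EOG-sEMG,4,4,50.0,11.6,1.45
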