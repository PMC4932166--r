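participant,experience,mean_time_s,sd_s,miss_rate_pct
K.I,experienced,42.0,3.1,0.0
K.M,experienced,35.8,5.0,0.0
R.K,experienced,60.2,12.4,3.5
T.T,experienced,53.2,13.0,2.5
K.G,experienced,61.0,15.5,5.0
T.N,experienced,43.2,2.7,0.0
M.F,inexperienced,68.6,5.5,0.0
M.S,inexperienced,36.6,5.2,2.0
R.K2,inexperienced,49.4,19.8,0.0
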