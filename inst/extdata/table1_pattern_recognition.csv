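subject,pattern,trials,correct,reject
K.G,right,9,8,1
T.N,right,9,9,0
M.Y,right,9,9,0
K.N,right,9,9,0
M.F,right,9,9,0
R.K,right,9,8,0
K.M,right,9,7,2
T.T,right,9,9,0
K.G,left,9,9,0
T.N,left,9,9,0
M.Y,left,9,8,0
K.N,left,9,9,0
M.F,left,9,9,0
R.K,left,9,9,0
K.M,left,9,8,1
T.T,left,9,9,0
K.G,right_blink,9,9,0
T.N,right_blink,9,9,0
M.Y,right_blink,9,9,0
K.N,right_blink,9,9,0
M.F,right_blink,9,9,0
R.K,right_blink,9,7,0
K.M,right_blink,9,8,0
T.T,right_blink,9,9,0
K.G,left_blink,9,9,0
T.N,left_blink,9,7,0
M.Y,left_blink,9,8,0
K.N,left_blink,9,9,0
M.F,left_blink,9,9,0
R.K,left_blink,9,7,0
K.M,left_blink,9,9,0
T.T,left_blink,9,9,0
K.G,bite,9,4,5
T.N,bite,9,8,1
M.Y,bite,9,4,5
K.N,bite,9,8,1
M.F,bite,9,3,6
R.K,bite,9,9,0
K.M,bite,9,5,4
T.T,bite,9,7,2
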