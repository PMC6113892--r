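item,C,A1,A2,A3,A4,A5
R040Q02,2,1,0,1,0,0
R040Q03A,2,1,0,1,1,0
R040Q04,2,0,1,1,1,0
R040Q06,2,1,0,1,0,0
R077Q03,3,0,1,0,1,1
R077Q04,2,1,1,1,0,0
R077Q05,3,0,1,1,1,0
R077Q06,2,0,1,0,0,1
R088Q01,2,0,1,1,0,0
R088Q03,3,1,0,1,0,0
R088Q04T,3,1,0,1,0,0
R088Q05T,2,0,1,1,1,0
R088Q07,2,0,1,0,0,1
R216Q01,2,0,1,0,0,0
R216Q02,2,1,0,0,0,1
R216Q03T,2,0,1,1,0,0
R216Q04,2,0,1,1,0,0
R216Q06,2,0,1,0,1,0
R236Q01,2,1,0,1,0,0
R236Q02,3,0,0,1,1,0
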