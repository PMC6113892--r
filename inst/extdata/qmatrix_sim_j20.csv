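item,A1,A2,A3,A4,A5
item1,1,0,0,0,0
item2,0,1,0,0,0
item3,0,0,1,0,0
item4,0,0,0,1,0
item5,0,0,0,0,1
item6,1,1,0,0,0
item7,1,0,0,0,1
item8,0,1,1,0,0
item9,0,0,1,1,0
item10,0,0,0,1,1
item11,1,1,1,0,0
item12,1,1,0,0,1
item13,1,0,0,1,1
item14,0,1,1,1,0
item15,0,0,1,1,1
item16,1,0,1,0,0
item17,1,0,0,1,0
item18,0,1,0,1,0
item19,0,1,0,0,1
item20,0,0,1,0,1
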