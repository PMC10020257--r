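arm,old_category,lt6,ge6_lt12,ge12_lt20,ge20_lt25,ge25,total
case,<6%,38,32,11,3,13,97
case,>=6 to <12%,98,122,117,49,193,579
case,>=12 to <20%,17,37,30,16,69,169
case,>=20 to <25%,2,3,9,1,13,28
case,>=25%,0,0,1,0,7,8
case,Total,155,194,168,69,295,881
control,<6%,132,46,37,8,18,241
control,>=6 to <12%,292,235,153,59,130,869
control,>=12 to <20%,40,43,40,15,46,184
control,>=20 to <25%,4,1,6,2,16,29
control,>=25%,0,0,1,0,3,4
control,Total,468,325,237,84,213,1327
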