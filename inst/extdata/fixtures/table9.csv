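arm,old_category,lt6,ge6_lt12,ge12_lt20,ge20_lt25,ge25,total
case,<6%,5,3,3,0,4,15
case,>=6 to <12%,11,15,15,8,12,61
case,>=12 to <20%,4,7,4,4,8,27
case,>=20 to <25%,0,0,1,0,2,3
case,>=25%,0,0,0,0,0,0
case,Total,20,25,23,12,26,106
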