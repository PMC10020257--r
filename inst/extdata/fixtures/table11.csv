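arm,old_category,lt6,ge6_lt12,ge12_lt20,ge20_lt25,ge25,total
case,<6%,9,11,4,1,5,30
case,>=6 to <12%,23,35,37,12,44,151
case,>=12 to <20%,3,15,7,7,20,52
case,>=20 to <25%,0,0,2,0,3,5
case,>=25%,0,0,0,0,1,1
case,Total,35,61,50,20,73,239
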