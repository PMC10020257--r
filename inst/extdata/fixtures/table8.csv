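arm,old_category,lt6,ge6_lt12,ge12_lt20,ge20_lt25,ge25,total
case,<6%,29,23,5,2,8,67
case,>=6 to <12%,53,74,72,31,136,366
case,>=12 to <20%,11,22,21,9,44,107
case,>=20 to <25%,2,3,5,1,6,17
case,>=25%,0,0,1,0,4,5
case,Total,95,122,104,43,198,562
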