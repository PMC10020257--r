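arm,old_category,lt6,ge6_lt12,ge12_lt20,ge20_lt25,ge25,total
case,<6%,25,17,4,1,6,53
case,>=6 to <12%,48,65,57,29,109,308
case,>=12 to <20%,9,17,17,5,35,83
case,>=20 to <25%,2,3,4,1,6,16
case,>=25%,0,0,1,0,5,6
case,Total,84,102,83,36,161,466
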