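arm,old_category,lt1,ge1_lt1.67,ge1.67_lt3,ge3,total
case,<1%,5,8,7,5,25
case,>=1 to <1.67%,14,9,12,18,53
case,>=1.67 to <3%,4,8,10,27,49
case,>=3%,1,1,5,6,13
case,Total,24,26,34,56,140
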