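arm,old_category,lt1,ge1_lt1.67,ge1.67_lt3,ge3,total
case,<1%,15,11,15,32,73
case,>=1 to <1.67%,50,47,77,162,336
case,>=1.67 to <3%,22,33,51,129,235
case,>=3%,3,1,7,52,63
case,Total,90,92,150,375,707
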