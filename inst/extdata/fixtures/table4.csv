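arm,old_category,lt1,ge1_lt1.67,ge1.67_lt3,ge3,total
case,<1%,25,28,31,39,123
case,>=1 to <1.67%,92,70,115,234,511
case,>=1.67 to <3%,37,54,79,228,398
case,>=3%,6,2,15,76,99
case,Total,160,154,240,577,1131
control,<1%,96,34,41,36,207
control,>=1 to <1.67%,231,146,163,229,769
control,>=1.67 to <3%,131,117,134,209,591
control,>=3%,14,21,23,75,133
control,Total,472,318,361,549,1700
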