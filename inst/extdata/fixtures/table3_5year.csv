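age_band,n,brisk_expected,brisk_observed,gail_expected,gail_observed
<45,24,0.32,0.23,0.20,0.23
45-49,180,2.27,2.06,1.70,2.06
50-54,273,4.13,3.58,3.19,3.58
55-59,342,6.89,5.30,4.80,5.30
60-64,441,9.13,8.76,7.67,8.76
65-69,317,6.51,7.68,6.02,7.68
70-74,97,1.74,2.50,1.90,2.52
75+,26,0.78,0.63,0.53,0.63
Total,1700,31.78,30.74,26.01,30.75
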