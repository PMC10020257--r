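age_band,n,brisk_expected,brisk_observed,ibis_expected,ibis_observed
<45,24,4.28,3.23,2.78,3.58
45-49,180,23.67,22.90,17.25,23.24
50-54,273,32.54,32.28,22.64,30.32
55-59,342,41.10,35.96,23.79,33.26
60-64,441,37.52,39.54,26.94,38.01
65-69,317,18.78,22.12,14.49,20.30
70-74,97,3.33,4.42,3.62,5.11
75+,26,0.60,0.51,0.66,0.76
Total,1700,161.83,160.96,112.18,154.59
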