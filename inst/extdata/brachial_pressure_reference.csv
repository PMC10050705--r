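age,sbp_mean,sbp_sd,dbp_mean,dbp_sd
25,124,10,75,8
35,123,10,77,7
45,125,9,79,6
55,125,9,79,6
65,126,9,78,6
75,127,9,76,6
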