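mass_g,s_mGy_per_MBq_h
0.01,5560.2976
0.02,2878.1906
0.05,1205.2483
0.1,623.87566
0.2,322.93829
0.5,135.23109
1,70
2,36.234272
5,15.173177
10,7.8541292
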