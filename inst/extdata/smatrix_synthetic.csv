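target,liver,kidneys,spleen,lungs,brain,stomach,intestines,mass_g,weight
liver,0.03888889,0.00116667,0.00116667,0.00116667,0.00116667,0.00116667,0.00116667,1800,0.0909090909999999
kidneys,0.00677419,0.22580645,0.00677419,0.00677419,0.00677419,0.00677419,0.00677419,310,0.0454545455
spleen,0.014,0.014,0.46666667,0.014,0.014,0.014,0.014,150,0.0227272727
lungs,0.00175,0.00175,0.00175,0.05833333,0.00175,0.00175,0.00175,1200,0.2727272727
brain,0.0015,0.0015,0.0015,0.0015,0.05,0.0015,0.0015,1400,0.0227272727
stomach,0.00525,0.00525,0.00525,0.00525,0.00525,0.175,0.00525,400,0.2727272727
intestines,0.0021,0.0021,0.0021,0.0021,0.0021,0.0021,0.07,1000,0.2727272727
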