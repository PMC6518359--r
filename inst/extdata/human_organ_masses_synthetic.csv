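region,mass_g
liver,1800
kidneys,310
spleen,150
lungs,1200
brain,1400
stomach,400
intestines,1000
total_body,73000
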