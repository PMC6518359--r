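region,mass_g
tumor,0.2
liver,1.3
kidneys,0.4
spleen,0.1
lungs,0.15
brain,0.4
stomach,0.5
intestines,2
total_body,25
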