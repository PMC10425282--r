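condition,basis,mean_1e6_cells_per_g,sd_1e6_cells_per_g
low,carbon,128.81,78.24
high,carbon,10.12,1.39
low,nitrogen,3.68,2.24
high,nitrogen,4.15,0.55
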