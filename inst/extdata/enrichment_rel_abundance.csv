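taxon,condition,mean_pct,sd_pct
Methylocystis,high,47.6,1.5
Methylocystis,low,2.1,1.7
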