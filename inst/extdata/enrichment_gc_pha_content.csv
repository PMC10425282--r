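core,method,pha_pct_mm
1,gc,13.47
2,gc,9.27
3,gc,14.95
1,microscopy,10.64
2,microscopy,7.23
3,microscopy,14.19
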