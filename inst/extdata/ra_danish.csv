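zygosity,y11,yd,y00
MZ,4,58,7517
DZ,2,126,11666
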