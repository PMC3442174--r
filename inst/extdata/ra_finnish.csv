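zygosity,y11,yd,y00
MZ,9,64,4064
DZ,6,167,8983
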