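zygosity,y11,yd,y00
MZ,3,8,4474
DZ,1,14,8164
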