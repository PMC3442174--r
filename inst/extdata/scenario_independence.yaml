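# 100,000 pairs per zygosity, prevalence 1%, complete independence
pi: 0.01
q_mz: 0.01
q_dz: 0.01
n_mz: 100000
n_dz: 100000
seed: 1
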