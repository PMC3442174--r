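# familial clustering: rare trait with strong MZ, mild DZ concordance
pi: 0.01
q_mz: 0.40
q_dz: 0.10
n_mz: 4000
n_dz: 6000
seed: 1
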