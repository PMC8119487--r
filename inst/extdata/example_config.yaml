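# Pipeline configuration: simulate -> arta -> feature-array
seed: 42
n_families: 4
generations: 4
visits: 3
profile: average
reference_profile: average
alpha: 0.05
max_af: 2.0e-05
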