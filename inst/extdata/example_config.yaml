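# Example run configuration (synthetic study, reduced to one salt condition)
constructs: [WT, R2Q, R8Q, R17Q, R26Q, R2/8/17/26Q]
salts_mM: [0]
seed: 7
noise_fraction: 0.02
overlap_criterion: quadrature
region_k: 1
params:
  f_salt: 0.65
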