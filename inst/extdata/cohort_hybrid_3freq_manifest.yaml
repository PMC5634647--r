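model: hybrid_3freq
seed: 20170928.0
params:
  wMB:
  - 0.5
  - 0.5
  - 0.5
  alpha_MF: 0.5
  alpha_MB: 0.5
  beta: 5.0
  lam: 0.5
  stay_bias: 0.2
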