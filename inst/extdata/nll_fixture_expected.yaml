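params:
  wMB: 0.6
  alpha_MF: 0.4
  alpha_MB: 0.7
  beta: 3.0
  lam: 0.5
  stay_bias: 0.2
nll: 1.760910163842809
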