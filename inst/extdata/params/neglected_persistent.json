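{
  "mu": 0.18,
  "alpha1": 0.6,
  "alpha2": 0.18,
  "alpha3": 0.18,
  "beta1": 0.5,
  "beta2": 0.05,
  "beta3": 0.15,
  "gamma1": 0.05,
  "gamma2": 0.15,
  "epsilon": 0
}
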