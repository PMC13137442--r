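{
  "mu": 0.18,
  "alpha1": 0.5,
  "alpha2": 0.24,
  "alpha3": 0.24,
  "beta1": 0.45,
  "beta2": 0.2,
  "beta3": 0.05,
  "gamma1": 0.05,
  "gamma2": 0.15,
  "epsilon": 0.08
}
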