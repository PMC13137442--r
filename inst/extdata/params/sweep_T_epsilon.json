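{
  "mu": 0.18,
  "alpha1": 0.7,
  "alpha2": 0.35,
  "alpha3": 0.2,
  "beta1": 0.4,
  "beta2": 0.2,
  "beta3": 0.15,
  "gamma1": 0.05,
  "gamma2": 0.05,
  "epsilon": 0.05
}
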