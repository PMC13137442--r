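{
  "mu": 0.05,
  "alpha1": 0.5,
  "alpha2": 0.45,
  "alpha3": 0.05,
  "beta1": 0.2,
  "beta2": 0.3,
  "beta3": 0.1,
  "gamma1": 0.1,
  "gamma2": 0.4,
  "epsilon": 0.05
}
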