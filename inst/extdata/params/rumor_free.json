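{
  "mu": 0.28,
  "alpha1": 0.25,
  "alpha2": 0.35,
  "alpha3": 0.28,
  "beta1": 0.3,
  "beta2": 0.35,
  "beta3": 0.3,
  "gamma1": 0.3,
  "gamma2": 0.3,
  "epsilon": 0.3
}
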