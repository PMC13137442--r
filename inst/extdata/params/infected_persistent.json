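{
  "mu": 0.18,
  "alpha1": 0.2,
  "alpha2": 0.46,
  "alpha3": 0.25,
  "beta1": 0.25,
  "beta2": 0.3,
  "beta3": 0.15,
  "gamma1": 0.15,
  "gamma2": 0.05,
  "epsilon": 0.4
}
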