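{
  "mu": 0.001,
  "alpha1": 0.3553,
  "alpha2": 0.1168,
  "alpha3": 0.4315,
  "beta1": 0.4772,
  "beta2": 0.07,
  "beta3": 0.2351,
  "gamma1": 0.4984,
  "gamma2": 0.0023,
  "epsilon": 0.0951
}
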