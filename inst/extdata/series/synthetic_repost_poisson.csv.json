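{
  "bin_width": 1,
  "fit_window_end": 30,
  "validation_end": 65,
  "population": 12372
}
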