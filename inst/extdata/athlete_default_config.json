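{
  "stature_m": 1.85,
  "mass_kg": 100,
  "mu": 0.3,
  "g": 9.81
}
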