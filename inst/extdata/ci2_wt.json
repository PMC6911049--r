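{
  "variant": "CI2 wild type",
  "chem": { "dG0": 30.9, "Cm": 4.07 },
  "chevron": { "kf0": 44, "ku0": 1.9e-4, "mf": -0.78, "mu": 0.51 }
}
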