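{
  "variant": "CI2 engineered fold-switch variant",
  "chem": { "dG0": 10.9, "Cm": 1.28 },
  "chevron": { "kf0": 25, "ku0": 0.58, "mf": -0.89, "mu": 0.52 }
}
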