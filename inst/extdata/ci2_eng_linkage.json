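{
  "step_NS": { "Tm": 359, "dHm": 100, "dCp": 0, ".class": "thermal_step_params" },
  "step_NU": { "Tm": 337, "dHm": 300, "dCp": 0, ".class": "thermal_step_params" },
  "assoc_H": { "dG_ref": -170, "dH_ref": 60, "dCp": 0, "T_ref": 298, "n": 6, ".class": "assoc_step_params" },
  "assoc_H2": { "dG_ref": -23, "dH_ref": 0, "dCp": 0, "T_ref": 298, "n": 2, ".class": "assoc_step_params" },
  "bind_P": null,
  ".class": "linkage_params"
}
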