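{
  "name": "ankle_fracture_staged_fixation",
  "planned_steps": [
    "polytrauma_protocol",
    "external_fixation_CT_classification",
    "definitive_fixation"
  ],
  "expected_outcome": "full_recovery"
}
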