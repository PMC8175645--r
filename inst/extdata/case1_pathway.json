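{
  "name": "distal_femur_fracture_ORIF",
  "planned_steps": [
    "diagnosis_fracture_pattern_classification",
    "preop_planning_CT_plate_screws",
    "surgery_ORIF_plate_screws",
    "full_recovery_limb_geometry"
  ],
  "expected_outcome": "full_recovery"
}
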