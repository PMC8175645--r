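{"schema_version":"1","journey_id":"case_study_1","initial":{"history":["road_traffic_injury"],"exam":{"xray_lower_limbs":"distal_femur_fracture","ct_head_thorax_abdomen":"negative"},"medications":[],"admission_diagnosis":"distal_femur_fracture_right","complexity":["polytrauma"],"admission_type":"emergency","expected_outcome":"full_recovery"},"steps":[{"action":"diagnosis_fracture_pattern_classification","params":{"narrative":"correct diagnosis and fracture pattern classification"},"t":1},{"action":"under_imaging_no_CT","params":{"narrative":"under-imaging with no CT scan evaluation of the fracture"},"t":2},{"action":"preop_planning_xray_nail","params":{"narrative":"preoperative planning based only on X-ray; intramedullary nail indicated"},"t":3},{"action":"surgery_intramedullary_nailing","params":{"narrative":"surgical intervention with intramedullary nailing and screws"},"t":4}],"final":{"outcome":"full_recovery","health_conditions":{"limb_length":"restored"}},"facility":"hospital_A"}
{"schema_version":"1","journey_id":"case_study_2","initial":{"history":["road_traffic_injury","alcohol_abuse"],"exam":{"GCS":15,"heart_rate_bpm":100,"bp":"140/90","spo2_pct":99,"lactate":2.7,"ethanol":2.54},"medications":[],"admission_diagnosis":"ankle_fracture_right","complexity":["alcohol_abuse","polytrauma"],"admission_type":"emergency","expected_outcome":"full_recovery"},"steps":[{"action":"polytrauma_protocol","params":{"narrative":"polytrauma protocol: X-ray, CT total body, blood samples"},"t":1},{"action":"internal_fixation_no_CT","params":{"narrative":"incorrect preoperative planning with no CT; improper internal fixation"},"t":2},{"action":"fracture_malunion","params":{"narrative":"malunion of the fracture"},"t":3},{"action":"osteosynthesis_revision","params":{"narrative":"osteosynthesis review with bone deformity correction"},"t":4}],"final":{"outcome":"partial_articular_recovery_ankle","health_conditions":{"ankle_joint":"partial_recovery"}},"facility":"hospital_A"}
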