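{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "pathrisk/journey-log.schema.json",
  "title": "pathrisk journey log record",
  "description": "One intra-hospital patient journey. A journey log is a UTF-8 JSON-Lines file with one such object per line.",
  "type": "object",
  "required": ["schema_version", "journey_id", "initial", "steps", "final"],
  "properties": {
    "schema_version": {"const": "1"},
    "journey_id": {"type": "string", "minLength": 1},
    "initial": {
      "type": "object",
      "required": ["admission_diagnosis", "admission_type", "expected_outcome"],
      "properties": {
        "history": {"type": "array", "items": {"type": "string"}},
        "exam": {"type": "object"},
        "medications": {"type": "array", "items": {"type": "string"}},
        "admission_diagnosis": {"type": "string", "minLength": 1},
        "complexity": {"type": "array", "items": {"type": "string"}},
        "admission_type": {
          "enum": ["emergency", "elective", "day_hospital", "day_surgery"]
        },
        "expected_outcome": {"type": "string", "minLength": 1}
      }
    },
    "steps": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["action", "t"],
        "properties": {
          "action": {"type": "string", "minLength": 1},
          "params": {"type": "object"},
          "t": {"type": "integer"},
          "timestamp": {"type": "string"}
        }
      }
    },
    "final": {
      "type": "object",
      "required": ["outcome"],
      "properties": {
        "outcome": {"type": "string", "minLength": 1},
        "health_conditions": {"type": "object"}
      }
    },
    "facility": {"type": ["string", "null"]}
  }
}
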