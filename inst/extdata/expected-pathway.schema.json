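{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "pathrisk/expected-pathway.schema.json",
  "title": "pathrisk expected pathway",
  "type": "object",
  "required": ["name", "planned_steps", "expected_outcome"],
  "properties": {
    "name": {"type": "string", "minLength": 1},
    "planned_steps": {
      "type": "array",
      "minItems": 1,
      "items": {"type": "string", "minLength": 1}
    },
    "expected_outcome": {"type": "string", "minLength": 1}
  }
}
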