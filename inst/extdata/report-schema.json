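{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Drug prediction report",
  "type": "object",
  "required": ["subject_id", "plan", "excluded", "provenance"],
  "properties": {
    "subject_id": { "type": "string" },
    "plan": {
      "type": "array",
      "minItems": 1,
      "maxItems": 4,
      "items": {
        "type": "object",
        "required": ["drug", "tier", "gene", "event"],
        "properties": {
          "drug": { "type": "string" },
          "tier": { "type": "integer", "enum": [1, 2, 3] },
          "gene": { "type": "string" },
          "event": { "type": "string" },
          "score": { "type": "number" },
          "evidence": { "type": ["string", "null"] }
        }
      }
    },
    "excluded": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["drug", "reason"],
        "properties": {
          "drug": { "type": "string" },
          "reason": { "type": "string", "enum": ["resistance_veto", "interaction_conflict", "excluded_by_config"] }
        }
      }
    },
    "priority_regimen_used": { "type": ["string", "null"] },
    "provenance": {
      "type": "object",
      "required": ["tool", "version", "parameters", "seed"],
      "properties": {
        "tool": { "type": "string" },
        "version": { "type": "string" },
        "parameters": { "type": "object" },
        "seed": { "type": ["integer", "null"] }
      }
    }
  }
}
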