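{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "tapmem trial log",
  "description": "One smartphone memory-test trial: ordered tap events grouped into attempts, for one test stage of one subject-session.",
  "type": "object",
  "required": ["schema_version", "subject_id", "stage", "session_time", "attempts"],
  "properties": {
    "schema_version": { "type": "string", "const": "1.0" },
    "subject_id": { "type": "string" },
    "stage": {
      "type": "string",
      "enum": ["verbal_immediate", "verbal_delayed", "spatial_static", "spatial_dynamic"]
    },
    "session_time": { "type": "string", "format": "date-time" },
    "attempts": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["events"],
        "properties": {
          "level": { "type": "integer", "minimum": 4, "maximum": 8 },
          "pattern": {
            "type": "array",
            "items": { "type": "integer", "minimum": 0, "maximum": 15 },
            "uniqueItems": true
          },
          "cues": { "type": "array", "items": { "type": "string" } },
          "passed": { "type": "boolean" },
          "events": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["t", "action", "target", "correct"],
              "properties": {
                "t": {
                  "type": "integer",
                  "minimum": 0,
                  "description": "milliseconds since trial start; non-decreasing within the trial"
                },
                "action": { "type": "string", "enum": ["select", "deselect"] },
                "target": {
                  "type": "integer",
                  "minimum": 0,
                  "maximum": 15,
                  "description": "grid cell 0-15 (spatial) or option index 0-3 (verbal)"
                },
                "correct": { "type": "boolean" }
              }
            }
          }
        }
      }
    }
  },
  "additionalProperties": true
}
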