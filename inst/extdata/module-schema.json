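{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "bondnet module exchange document",
  "type": "object",
  "required": ["name", "components", "junctions", "bonds"],
  "properties": {
    "name": { "type": "string" },
    "components": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "kind"],
        "properties": {
          "id": { "type": "string" },
          "kind": { "enum": ["R", "C", "I", "Se", "Sf"] },
          "param": { "type": ["number", "null"] },
          "param_ref": { "type": ["string", "null"] },
          "units": { "type": ["string", "null"] }
        }
      }
    },
    "junctions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "kind"],
        "properties": {
          "id": { "type": "string" },
          "kind": { "enum": ["zero", "one"] }
        }
      }
    },
    "bonds": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "tail", "head"],
        "properties": {
          "id": { "type": "string" },
          "tail": { "type": "string" },
          "head": { "type": "string" }
        }
      }
    },
    "ports": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "junction", "kind"],
        "properties": {
          "id": { "type": "string" },
          "junction": { "type": "string" },
          "kind": { "enum": ["flow", "potential"] },
          "binding": { "type": ["string", "null"] }
        }
      }
    },
    "annotations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["variable", "property_term", "entity_term"],
        "properties": {
          "variable": { "type": "string" },
          "property_term": {
            "type": "string",
            "pattern": "^(potential|flow|time|parameter:.+)$"
          },
          "entity_term": { "type": "string" }
        }
      }
    }
  }
}
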