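{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Consortium DSH instance document",
  "type": "object",
  "required": ["schema_version", "worker_organisms", "vertices", "arcs",
               "sources", "targets", "weights"],
  "properties": {
    "schema_version": {"const": "1.0"},
    "worker_organisms": {
      "type": "array", "items": {"type": "string"}, "minItems": 1
    },
    "reference_reactions": {
      "type": "array", "items": {"type": "string"}
    },
    "vertices": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "compound", "organism"],
        "properties": {
          "id": {"type": "string"},
          "compound": {"type": "string"},
          "organism": {"type": "string"}
        }
      }
    },
    "arcs": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "reaction", "sources", "target", "weight",
                     "category", "organism"],
        "properties": {
          "id": {"type": "string"},
          "reaction": {"type": "string"},
          "sources": {
            "type": "array", "items": {"type": "string"}, "minItems": 1
          },
          "target": {"type": "string"},
          "weight": {"type": "number", "minimum": 0},
          "category": {
            "enum": ["endogenous", "insertion", "transition", "composite"]
          },
          "organism": {"type": "string"}
        }
      }
    },
    "sources": {"type": "array", "items": {"type": "string"}},
    "targets": {"type": "array", "items": {"type": "string"}, "minItems": 1},
    "weights": {
      "type": "object",
      "required": ["w_worker", "w_other", "w_transition"],
      "properties": {
        "w_worker": {"type": "number", "minimum": 0},
        "w_other": {"type": "number", "minimum": 0},
        "w_transition": {"type": "number", "minimum": 0},
        "overrides": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["category", "key", "weight"],
            "properties": {
              "category": {"enum": ["endogenous", "insertion", "transition"]},
              "key": {"type": "string"},
              "weight": {"type": "number", "minimum": 0}
            }
          }
        }
      }
    }
  }
}
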