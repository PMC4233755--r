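{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "domainsim model document",
  "description": "Versioned document format for three-level biological domain models. Guard expressions use the grammar: atom := NAME | 'δ(' NAME ')' | 'λ(' NAME ')' (ASCII aliases delta/lambda accepted); expr := atom | expr '&' expr | expr '|' expr | '(' expr ')'; '&' binds tighter than '|'; the empty string is the always-true guard.",
  "type": "object",
  "required": ["compartments", "migration_rules", "entities",
               "state_machines", "perspectives", "research_context",
               "parameters"],
  "properties": {
    "version": {"type": "integer"},
    "compartments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name"],
        "properties": {
          "name": {"type": "string", "minLength": 1},
          "description": {"type": "string"}
        }
      }
    },
    "migration_rules": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["entity_type", "from", "to"],
        "properties": {
          "entity_type": {"type": "string"},
          "from": {"type": "string"},
          "to": {"type": "string"},
          "state_condition": {"type": "string",
            "description": "guard over active-state predicate atoms only"}
        }
      }
    },
    "entities": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "category"],
        "properties": {
          "name": {"type": "string", "minLength": 1},
          "category": {"enum": ["cell", "molecule"]},
          "description": {"type": "string"}
        }
      }
    },
    "state_machines": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["entity_type", "regions"],
        "properties": {
          "entity_type": {"type": "string"},
          "regions": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["name", "initial", "states"],
              "properties": {
                "name": {"type": "string"},
                "initial": {"type": "string"},
                "states": {"type": "array", "minItems": 1,
                           "items": {"$ref": "#/definitions/state"}}
              }
            }
          },
          "transitions": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["source", "target"],
              "properties": {
                "source": {"type": "string"},
                "target": {"type": "string"},
                "guard": {"type": "string"},
                "actions": {"type": "array", "items": {"type": "string"}}
              }
            }
          },
          "death_states": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "perspectives": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "expands", "nodes"],
        "properties": {
          "name": {"type": "string"},
          "expands": {"type": "array", "items": {"type": "string"}},
          "nodes": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["name", "kind"],
              "properties": {
                "name": {"type": "string"},
                "kind": {"enum": ["start", "action", "decision", "merge",
                                  "fork", "join", "end"]},
                "swim_lane": {"type": "string"},
                "subject": {"type": "string"}
              }
            }
          },
          "sequential": {"type": "array"},
          "propagating": {"type": "array"},
          "interrupts": {"type": "array"},
          "contributory": {"type": "array"}
        }
      }
    },
    "research_context": {
      "type": "object",
      "required": ["phenomena", "behaviours", "components", "links"],
      "properties": {
        "phenomena": {"type": "array",
          "items": {"type": "object", "required": ["name", "in_scope"]}},
        "behaviours": {"type": "array",
          "items": {"type": "object", "required": ["name", "emergent"]}},
        "components": {"type": "array", "items": {"type": "string"}},
        "links": {"type": "array",
          "items": {"type": "object",
                    "required": ["source", "target", "polarity"],
                    "properties": {"polarity":
                      {"enum": ["autoimmune", "regulatory", "neutral"]}}}}
      }
    },
    "parameters": {
      "type": "object",
      "additionalProperties": {"type": "number"}
    },
    "location_region": {"type": "string", "default": "location"},
    "binding_declarations": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["partner_entity", "partner_state"]
      }
    },
    "interaction_rules": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "actor", "partner", "effect", "rate"],
        "properties": {
          "effect": {"enum": ["assert_predicate", "kill", "spawn"]}
        }
      }
    }
  },
  "definitions": {
    "state": {
      "type": "object",
      "required": ["name", "kind"],
      "properties": {
        "name": {"type": "string", "minLength": 1},
        "kind": {"enum": ["atomic", "composite", "isolated"]},
        "initial": {"type": "string"},
        "substates": {"type": "array",
                      "items": {"$ref": "#/definitions/state"}},
        "entry_actions": {"type": "array", "items": {"type": "string"}},
        "exit_actions": {"type": "array", "items": {"type": "string"}},
        "emissions": {"type": "array", "items": {"type": "string"}}
      }
    }
  }
}
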