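{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "competitron run configuration",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "schema_version": {"type": "string"},
    "mode": {"enum": ["supervised", "unsupervised"]},
    "neurons": {"type": "integer", "minimum": 1},
    "eta": {"type": "number", "minimum": 0, "maximum": 1},
    "nu": {"type": "number", "minimum": 0},
    "k": {"type": "number", "exclusiveMinimum": 0},
    "g": {"type": "number", "exclusiveMinimum": 0},
    "epochs": {"type": "integer", "minimum": 1},
    "seed": {"type": "integer"},
    "max_steps": {"type": "integer", "minimum": 1},
    "theta_fire": {"type": "number", "exclusiveMinimum": 0.5, "exclusiveMaximum": 1},
    "complement": {"type": "boolean"},
    "normalize": {"type": "boolean"},
    "eps": {"type": "number", "exclusiveMinimum": 0},
    "init_weight_max": {"type": "number", "minimum": 0},
    "init_shift": {"type": "number", "minimum": 0, "maximum": 1},
    "autapse_init": {"type": "number", "minimum": 0, "maximum": 1},
    "shuffle": {"type": "boolean"},
    "amp": {"type": "boolean"},
    "amp_eps": {"type": "number", "exclusiveMinimum": 0},
    "amp_clip": {"type": "array", "items": {"type": "number"}, "minItems": 2, "maxItems": 2},
    "predict_adapt": {"type": "boolean"}
  }
}
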