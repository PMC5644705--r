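{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "turntaking attempt report",
  "type": "object",
  "required": ["attempt_id", "n_significant_carers", "carers", "warnings"],
  "properties": {
    "attempt_id": {"type": "string"},
    "n_significant_carers": {"type": "integer", "minimum": 1},
    "carers": {"type": "array"},
    "excluded": {"type": "array"},
    "skipped": {"type": ["string", "null"]},
    "warnings": {"type": "array", "items": {"type": "string"}},
    "alternation": {
      "type": "object",
      "required": ["proportion", "n_alt", "n_rep"],
      "properties": {
        "proportion": {"type": ["number", "null"], "minimum": 0, "maximum": 1},
        "n_alt": {"type": "integer"},
        "n_rep": {"type": "integer"}
      }
    },
    "runs_test": {
      "type": "object",
      "required": ["R_obs", "E_R", "p"],
      "properties": {
        "R_obs": {"type": "integer"},
        "E_R": {"type": "number"},
        "Var_R": {"type": "number"},
        "z": {"type": ["number", "null"]},
        "p": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "models": {"type": "array"},
    "lambda": {"type": "object"},
    "mu": {"type": "object"},
    "group_ratio": {"type": ["number", "null"]},
    "wilcoxon_p": {"type": ["number", "null"]},
    "randomization": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["statistic", "observed", "p_active", "passive_flag"],
        "properties": {
          "statistic": {"type": "string"},
          "observed": {"type": ["number", "null"]},
          "p_active": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
          "passive_flag": {"type": "boolean"},
          "null_summary": {"type": "object"}
        }
      }
    },
    "ivi": {"type": "object"},
    "ordering": {"type": "object"},
    "bout_test": {"type": "object"}
  }
}
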