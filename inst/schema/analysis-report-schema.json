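{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "quenchbind analysis report",
  "type": "object",
  "required": ["units", "warnings", "errors", "provenance"],
  "additionalProperties": false,
  "properties": {
    "stern_volmer": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["k_sv", "intercept", "r_squared", "temperature"],
        "properties": {
          "k_sv": {"type": "number"},
          "intercept": {"type": "number"},
          "k_sv_stderr": {"type": ["number", "null"]},
          "intercept_stderr": {"type": ["number", "null"]},
          "r_squared": {"type": "number", "minimum": 0, "maximum": 1},
          "temperature": {"type": "number", "exclusiveMinimum": 0},
          "n_points": {"type": "integer"}
        }
      }
    },
    "double_log": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["k_a", "n_sites", "r_squared", "temperature"],
        "properties": {
          "k_a": {"type": "number", "exclusiveMinimum": 0},
          "n_sites": {"type": "number", "exclusiveMinimum": 0},
          "k_a_stderr": {"type": ["number", "null"]},
          "n_sites_stderr": {"type": ["number", "null"]},
          "r_squared": {"type": "number"},
          "temperature": {"type": "number"},
          "points_used": {"type": "integer"},
          "points_dropped": {"type": "integer"},
          "bracket_denominator": {"enum": ["F", "F0"]}
        }
      }
    },
    "vant_hoff": {
      "type": "object",
      "required": ["delta_h", "delta_s", "gas_constant"],
      "properties": {
        "delta_h": {"type": "number"},
        "delta_s": {"type": "number"},
        "delta_h_stderr": {"type": ["number", "null"]},
        "delta_s_stderr": {"type": ["number", "null"]},
        "r_squared": {"type": "number"},
        "gas_constant": {"const": 8.314},
        "temperatures": {"type": "array", "items": {"type": "number"}},
        "ka_values": {"type": "array", "items": {"type": "number"}}
      }
    },
    "thermo": {
      "type": "object",
      "properties": {
        "table": {"type": "array"},
        "force_label": {"type": "string"}
      }
    },
    "quenching": {
      "type": "object",
      "properties": {
        "mechanism": {"enum": ["static", "dynamic", "indeterminate"]},
        "ksv_trend": {"type": "integer"},
        "mean_lifetime_ratio_deviation": {"type": ["number", "null"]},
        "ratio_threshold": {"type": "number"}
      }
    },
    "idf": {
      "type": "object",
      "properties": {
        "points": {"type": "array"},
        "fit": {
          "type": "object",
          "properties": {
            "k_b": {"type": "number", "exclusiveMinimum": 0},
            "n_sites": {"type": "number", "exclusiveMinimum": 0},
            "r_squared": {"type": "number"},
            "cooperativity_flag": {
              "enum": ["non_cooperative_linear", "nonlinear"]
            }
          }
        }
      }
    },
    "lifetime": {
      "type": "object",
      "properties": {
        "tau0": {"type": ["number", "null"]},
        "fits": {"type": "array"},
        "tau0_over_tau": {"type": "array", "items": {"type": "number"}}
      }
    },
    "cd": {"type": "array"},
    "docking": {"type": "array"},
    "units": {"type": "object"},
    "warnings": {"type": "array", "items": {"type": "string"}},
    "errors": {"type": "array", "items": {"type": "string"}},
    "provenance": {
      "type": "object",
      "required": ["package", "version"],
      "properties": {
        "package": {"const": "quenchbind"},
        "version": {"type": "string"},
        "timestamp": {"type": "string"},
        "config": {"type": "object"}
      }
    }
  }
}
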