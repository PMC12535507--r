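{
  "report": {
    "required": {
      "runs": "list",
      "aggregate": "list",
      "config": "list",
      "data_fingerprint": "string",
      "wall_time_s": "number",
      "versions": "list"
    }
  },
  "run": {
    "required": {
      "mechanism": "string",
      "alpha": "number",
      "seed": "number",
      "leaf_accuracy": "number",
      "severity": "number",
      "per_level_accuracy": "number"
    }
  },
  "aggregate": {
    "required": {
      "mechanism": "string",
      "alpha": "number",
      "n_seeds": "number",
      "severity_mean": "number",
      "severity_sd": "number",
      "accuracy_mean": "number",
      "accuracy_sd": "number"
    }
  }
}
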