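{
  "schema": "ifscreen-rule-tree/1",
  "name": "fixed_tree_B",
  "predictors": ["omega1_bpm", "omegai1"],
  "node": {
    "feature": "omegai1",
    "op": ">",
    "threshold": 1.6,
    "if_true": {"label": "low"},
    "if_false": {
      "feature": "omegai1",
      "op": "<",
      "threshold": 1.22,
      "if_true": {"label": "normal"},
      "if_false": {
        "feature": "omega1_bpm",
        "op": ">",
        "threshold": 107.6,
        "if_true": {"label": "low"},
        "if_false": {"label": "normal"}
      }
    }
  }
}
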