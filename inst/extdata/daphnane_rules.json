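{
  "name": "daphnane_toy_rules",
  "auto_from_library": true,
  "settings": {
    "tol_ppm": 5,
    "mz_range": [200, 400],
    "noise_threshold": 0.1,
    "min_matching_ions": 2,
    "top_n": 3,
    "polarity": "positive",
    "rt_tol": 0.1,
    "cosine_tol_ppm": 10,
    "rdbe_range": [0, 40],
    "db_bounds": {"C": [0, 50], "H": [0, 80], "O": [0, 15], "N": [0, 0]}
  },
  "rules": [
    {
      "id": "IV:orthoester",
      "slot": "module_IV",
      "submodule": "IV1",
      "evidence": [
        {"type": "ms1_pattern", "pattern": "protonated_dominant", "weight": 0}
      ]
    },
    {
      "id": "IV:triol",
      "slot": "module_IV",
      "submodule": "IV2",
      "evidence": [
        {"type": "ms1_pattern", "pattern": "dehydration_dominant", "weight": 0}
      ]
    }
  ]
}
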