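[
  {"name": "[M+H]+", "polarity": "positive", "gained": "H", "lost": "", "charge": 1},
  {"name": "[M+NH4]+", "polarity": "positive", "gained": "NH4", "lost": "", "charge": 1},
  {"name": "[M+H-H2O]+", "polarity": "positive", "gained": "H", "lost": "H2O", "charge": 1},
  {"name": "[M+CH3CN+H]+", "polarity": "positive", "gained": "C2H4N", "lost": "", "charge": 1},
  {"name": "[M+CH3NH2+H]+", "polarity": "positive", "gained": "CH6N", "lost": "", "charge": 1},
  {"name": "[M-H]-", "polarity": "negative", "gained": "", "lost": "H", "charge": -1},
  {"name": "[M+HCOO]-", "polarity": "negative", "gained": "CHO2", "lost": "", "charge": -1}
]
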