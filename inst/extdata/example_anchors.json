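[
  {"label": "autonomous retinal screening (synthetic anchor)", "points": 100, "payment": 45, "conversion_factor": 30},
  {"label": "computer-assisted long-term ECG analysis (synthetic anchor)", "points": 100, "rvu": 1.5}
]
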