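{
  "prevalence": 0.10,
  "soc": {"sensitivity": 0.85, "specificity": 0.90},
  "ai": {"sensitivity": 0.90, "specificity": 0.93},
  "cost_fn": 2000,
  "cost_fp": 150,
  "ai_fee": 12,
  "minutes_saved": 3,
  "n": 1000
}
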