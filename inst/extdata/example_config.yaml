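regime: ebm-simplified
rounding: half_up
factor_cap: 2
default_n: 1000
output_format: json
regimes:
  flat-unit:
    euro_per_point: 1.0
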