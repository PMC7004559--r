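tube:
  volume_ml: 1.84
  radius_mm: 0.5
dose_mg: 51.52
t0_clock: '10:15'
drug: LOHP
segments:
- start_h: 0.0
  duration_h: 11.5
  shape: half_sin_squared
  peak_rate_ml_h: 2.9992
  solution: drug
  stock_mg_per_ml: 3.0
  period_h: 11.5
  offset_h: 0.0
- start_h: 11.5
  duration_h: 0.5
  shape: half_sin_squared
  peak_rate_ml_h: 13.3952
  solution: glucose
  stock_mg_per_ml: 0.0
  period_h: 0.5
  offset_h: 0.0
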