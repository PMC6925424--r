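# Reference habitat-pair scenario: cold, thermally damped natal stream
# feeding a warmer, seasonally lagged lake.  Masses in g, temperatures in
# degrees C, days as day of year.  Identical to default_scenario(delta_g = 5).
season_stream:
  mean_temp: 5.5
  amplitude: 1.5
  peak_day: 215
  period: 365
season_lake:
  mean_temp: 12.0
  amplitude: 8.5
  peak_day: 240
  period: 365
growth:
  c_max: 2.8            # % body mass / day at 1 g and optimal temperature
  mass_exponent: 0.31
  temp_lower: 3.6
  temp_opt: 13.1
  temp_upper: 19.5
predation_lake:
  p_max: 8.0
  alpha_small: 3.5      # vulnerability of a 112.3 mm (14.16 g) fish
  alpha_large: 1.5      # vulnerability of a 216.4 mm (101.34 g) fish
  size_range: [14.162478667, 101.337869440]
predation_stream:
  p_max: 6.0
  alpha_small: 0.55     # size-independent stream predation
  alpha_large: 0.55
  size_range: [14.162478667, 101.337869440]
delta_g: 5.0
day_window: [40, 182]
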