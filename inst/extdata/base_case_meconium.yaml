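comparison: meconium
cohort:
  size: 100.0
  prevalence: 0.663
tool:
  name: meconium
  sensitivity: 0.924
  specificity: 0.515
  unit_cost: 175.0
  screen_age: 0.0
  lag_to_testing: 5.0
costs:
  first_year: 15976.0
  diagnosed_annual: 3426.0
  undiagnosed_annual: 2713.0
  no_fasd_annual: 3101.0
  diagnostic_testing: 3870.0
  basis: pre_inflation
mortality:
  smr_diagnosed: 3.15
  undiagnosed_multiplier: 1.1
  smr_no_fasd: 3.15
time:
  discount_rate: 0.015
  end_age: 18.0
future_diagnosis:
  rate: 0.05
  model: hazard
  start: at_testing
inflation:
  factor: 1.268464750396749
  inflate_no_fasd: yes
model:
  half_cycle: trapezoid
  pending_fasd_cost: undiagnosed
  use_inflated_costs: yes
  diagnostic_sensitivity: 1.0
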