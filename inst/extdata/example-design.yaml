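# Example configuration: Scenario 5 with back-loaded (concave) accrual.
# Load with: read_design_config(system.file("extdata", "example-design.yaml",
#                                           package = "enrichsim"))
design:
  tss: 330
  total_events: 270
  interim_fraction: 0.5
  alpha: 0.025
  eta_O: 1.0
  eta_P: 1.0
  R: 6
  F: 2
  decision_period: 0.2
  prevalence: 0.5
  hr_positive: 0.50
  hr_negative: 1.43
  control_survival: 0.2
  accrual: trunc_exp
  gamma: -2
simulation:
  n_reps: 1000
  master_seed: 1
  strategies: [typical, continued_O, continued_P, non_enriched]
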