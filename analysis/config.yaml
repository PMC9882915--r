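# Pipeline configuration for the analysis scripts (analysis/01...06).
# Keys mirror ccscreen::default_run_config(); unknown keys are rejected.
seed: 1
out_dir: results
mcmc:
  chains: 4
  warmup: 2500
  iter: 800
  thin: 20
lifetable:
  init: model
  start_age: 30
  start_year: 2005
  cycles: 15
rate_ratio:
  r1: 0.02
  n_women: 12500
  n_surveys: 4
  ages: [18, 29]
treatment:
  use_demo: true
sensitivity:
  year_min: ~
  whs_fixed_effect: false
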