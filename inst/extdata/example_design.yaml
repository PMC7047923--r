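# Example single-feature simulation design for the simulate-feature /
# simulate-community subcommands. Community subcommand also reads the
# features / diff_abun_features fields.
n_control: 20
n_treat: 20
control_mean: 2
num_timepoints: 7
t_interval: [0, 6]
asynch_time: false
missing_pct: 0.2
missing_per_subject: 2
miss_val: 0
seed: 42
trend:
  form: quadratic
  beta: [0, 3, -0.5]
covariance:
  structure: compound
  sigma: 1
  rho: 0.7
truncation:
  enabled: true
  a: 0
  acceptance_threshold: 0.1
  pilot_draws: 1000
features: 10
diff_abun_features: 4
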