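# Example sweep configuration for the sweep subcommand: a sigma x n x q grid
# crossed with a differential and a null trend form, scored by the bundled
# per-timepoint t-test detector.
repetitions: 5
detector: ttest
seed: 7
grids:
  sigma: [1, 2, 4]
  n_per_group: [10, 20]
  q: [3, 6]
trends:
  hockey_up: {form: L_up, beta: [1], ip: [3]}
  null_form: {form: none}
base_design:
  n_control: 10
  n_treat: 10
  control_mean: 2
  num_timepoints: 6
  t_interval: [0, 6]
  trend: {form: none}
  covariance: {structure: ar1, sigma: 1, rho: 0.7}
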