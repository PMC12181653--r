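# 10-node demonstration pipeline: sparse positive cross-lagged structure,
# moderate autoregression, screening and missingness at realistic survey
# rates. Runs end to end in a few minutes on one CPU.
seed: 1
threshold: 0.05
out_dir: clpnet-demo-output
simulation:
  truth:
    node_labels: [n01, n02, n03, n04, n05, n06, n07, n08, n09, n10]
    edge_density: 0.0889   # 8 of the 90 ordered off-diagonal pairs
    effect_size: 0.3
    autoregression: 0.3
    truth_seed: 7
    within_wave_corr: 0.3
  "config":
    "n": 2000
    missing_rate: 0.02
    screen_negative_rate: 0.22
    control_fail_rate: 0.07
estimator:
  n_folds: 10
  lambda_rule: min
bootstrap:
  n_boot: 200
  case_drop_n_boot: 25
  proportions: [0.1, 0.3, 0.5, 0.75]
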