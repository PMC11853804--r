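{
  "seed": 1,
  "bandit": {
    "outcome1_probs": [0.8, 0.2, 0.2]
  },
  "model": {
    "outcome1_probs": [0.8, 0.2, 0.2],
    "preference": 0.625,
    "gamma": 16,
    "alpha": 1,
    "policy_len": 2
  },
  "group": {
    "n_internal": 8,
    "aggregation": "probabilistic",
    "n_trials": 120
  },
  "fitting": {
    "prior_scale": 4,
    "n_chains": 4,
    "n_draws": 1000,
    "warmup": 1000
  },
  "recovery": {
    "alpha_grid": [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1, 1.5, 2],
    "n_seeds": 3,
    "n_trials": 500
  },
  "experiment": {
    "n_internal": [4, 8, 16, 100],
    "mean_alpha": [0.25, 0.5, 0.75],
    "n_seeds": 1,
    "n_trials": 500
  }
}
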