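{
  "seed": 20160901,
  "output_dir": "trialhist_demo",
  "task": {
    "n_trials_mean": 150,
    "n_trials_sd": 20
  },
  "cohort": {
    "n_mice": 2,
    "n_sessions": 3,
    "neurons_per_session": 3
  },
  "behavior": {
    "beta0": 0.1,
    "beta_odor_L": 3,
    "beta_odor_R": -3,
    "beta_choice": [0.7],
    "beta_outcome_L": [0.3],
    "beta_outcome_R": [-0.3],
    "cv_repeats": 5
  },
  "preference": {
    "n_perm": 200
  },
  "link": {
    "n_perm": 200
  },
  "inactivation": {
    "enabled": true,
    "n_sets": 2,
    "delta_bias": 0.8,
    "choice1_scale": 0.5,
    "n_trials": 200
  }
}
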