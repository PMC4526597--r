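{
  "experiment": "exp1",
  "p_common": 0.7,
  "walk_sd": 0.025,
  "walk_bounds": [0.25, 0.75],
  "reward_value": 0.25,
  "response_cost": 0.01,
  "n_training": 200,
  "n_stabilized": 0,
  "stabilized_probs": [0.9, 0.1],
  "n_nofeedback": 4,
  "n_test": 20,
  "response_window": 2.5,
  "max_run_length": 4
}
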