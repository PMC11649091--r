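{
  "scale": "ci",
  "sigma_pref": 15,
  "sigma_tuning": 11,
  "n_range": [7, 13],
  "theta_grid": [0, 15, 30, 45, 60, 75, 90],
  "n_segments": 1000,
  "K_out": 3,
  "K_in": 140,
  "R1": 1,
  "R2": 2,
  "L": 10,
  "delta_k_in_grid": [0.2, 0.5, 0.8, 1.1, 1.4, 1.7, 2],
  "R2_grid": [1.2, 1.5, 1.8, 2.1, 2.4, 2.7, 3],
  "ek_conditions": [0, 6, 18],
  "pd_trials": 5,
  "neuron_trials": 3,
  "neuron_generations": 2,
  "diffusion_t_total": 400
}
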