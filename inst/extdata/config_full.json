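{
  "scale": "full",
  "sigma_pref": 15,
  "sigma_tuning": 11,
  "n_range": [7, 13],
  "theta_grid": [0, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90],
  "n_segments": 10000,
  "K_out": 3,
  "K_in": 140,
  "R1": 1,
  "R2": 2,
  "L": 10,
  "delta_k_in_grid": [0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1, 1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9, 2],
  "R2_grid": [1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9, 2, 2.1, 2.2, 2.3, 2.4, 2.5, 2.6, 2.7, 2.8, 2.9, 3],
  "ek_conditions": [0, 6, 18],
  "pd_trials": 10,
  "neuron_trials": 15,
  "neuron_generations": 4,
  "diffusion_t_total": 1000
}
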