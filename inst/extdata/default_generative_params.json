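{
  "version": "2026.09-1",
  "comment": "Calibrated defaults for the synthetic cohort generator. Produced by scripts/calibrate.R (coarse grid search against the benchmark group statistics in calibration_targets()); do not edit by hand.",
  "control": {
    "n_participants": 30,
    "delta_increment_mean": [0.927, 1.133, 1.133],
    "delta_increment_sd": [0.65, 0.65, 0.65],
    "kappa_mean": 1.35,
    "kappa_sd": 0.3,
    "conf_gain_mean": 1.1,
    "conf_gain_sd": 0.35,
    "conf_offset": -0.8,
    "sigma_meta": 1,
    "missing_rate": 0.019,
    "clinical": {
      "spqb_cogper_mean": 2.5,
      "spqb_cogper_sd": 1.9,
      "spqb_inter_mean": 3,
      "spqb_inter_sd": 2.1,
      "spqb_disorg_mean": 1.8,
      "spqb_disorg_sd": 1.7
    }
  },
  "psychosis": {
    "n_participants": 30,
    "delta_increment_mean": [0.248, 0.284, 0.284],
    "delta_increment_sd": [0.65, 0.65, 0.65],
    "kappa_mean": 1.1,
    "kappa_sd": 0.3,
    "conf_gain_mean": 0,
    "conf_gain_sd": 0.7,
    "conf_offset": 1,
    "sigma_meta": 0.6,
    "missing_rate": 0.084,
    "clinical": {
      "panss_pos_mean": 15.1,
      "panss_pos_sd": 3.2,
      "panss_pos_coupling": 2.72,
      "panss_neg_mean": 15.2,
      "panss_neg_sd": 5.2,
      "panss_gen_mean": 32.5,
      "panss_gen_sd": 7
    }
  }
}
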