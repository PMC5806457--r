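# Example pipeline configuration.  Omitted fields keep package defaults;
# the master seed is mandatory.
seed: 20260929
design:
  n_replicates: 5
  n_timepoints: 13
  interval_h: 48
growth:
  n0: 2
  rate:
    wild_type: 0.50
    mutant: 0.35
  plant_effect_sd: 0.05
  young_age_days: 2
observers:
  n_exp: 5
  n_nexp: 4
citizens:
  pool_size: 40
  activity_skew: 1.0
analysis:
  outlier_s: 200
  sd_threshold: 1.0
  conf_threshold: 2.0
  n_trials: 500
  K: [1, 2, 3]
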