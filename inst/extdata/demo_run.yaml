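# Demo run: 4 samples (one per disease state), desk-scale detection settings.
# The simulated cohort carries a percent-level planted rare fraction, so the
# detection quantile is set accordingly (the detection_params() default of
# 99.5 targets the much sparser regime of real rare-cell assays).
seed: 1
cohort:
  n_per_state:
    MGUS: 1
    SMM: 1
    NDMM: 1
    RRMM: 1
detection:
  distance_quantile: 94
  max_rare_cluster_size: 0.1
stages:
  predict: false
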