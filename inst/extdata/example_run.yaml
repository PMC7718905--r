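# Example end-to-end run: simulate a two-group cohort and run the full
# battery.  `within_group_dispersion` is the heterogeneity knob.
spec:
  n_per_group: 20
  groups: [HC, SZ]
  sites: [siteA]
  n_ct_regions: 64
  n_sv_regions: 18
  within_group_dispersion: 0.5
  seed: 7
contrasts:
  - a: SZ
    b: HC
covariates: [age, sex]
subset_reps: 25
outlier_policy: tukey
seed: 7
output_dir: pbsi_example_run
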