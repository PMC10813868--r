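'n': 5110
seed: 1
preset: 'null'
covariate_params:
  age:
    mean: 59.4
    sd: 8.7
    min: 40.0
    max: 75.0
  sex:
    p_female: 0.494
  education:
    p:
    - 0.32
    - 0.284
    - 0.397
  bmi:
    mean: 26.6
    sd: 4.2
  diabetes:
    p:
    - 0.641
    - 0.147
    - 0.206
    - 0.006
  cvd:
    p_yes: 0.126
  wmh:
    median: 0.016
    q25: 0.005
    q75: 0.05
  age_wmh_cor: 0.0
quality_coeffs:
  dmri:
    isnr:
    - 0.0
    - -0.0
    - -0.0
    - 0.0
    - 0.0
    - 0.0
    - -0.0
    motion:
    - 0.0
    - -0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    mismatch:
    - 0.0
    - -0.0
    - -0.0
    - 0.0
    - -0.0
    - 0.0
    - 0.0
  fmri:
    isnr:
    - 0.0
    - -0.0
    - -0.0
    - 0.0
    - 0.0
    - -0.0
    - 0.0
    motion:
    - 0.0
    - -0.0
    - -0.0
    - 0.0
    - 0.0
    - -0.0
    - -0.0
    mismatch:
    - -0.0
    - 0.0
    - -0.0
    - -0.0
    - -0.0
    - 0.0
    - 0.0
quality_scale:
  dmri:
    isnr:
    - -22.0
    - 6.5
    motion:
    - 0.64
    - 0.16
    mismatch:
    - 0.087
    - 0.0092
  fmri:
    isnr:
    - -39.0
    - 11.0
    motion:
    - 0.13
    - 0.088
    mismatch:
    - 0.089
    - 0.0086
quality_cor_targets:
  metric1:
  - dmri_isnr
  - fmri_isnr
  metric2:
  - dmri_motion
  - fmri_motion
  r:
  - 0.0
  - 0.0
connectivity_coeffs:
  sc:
  - -0.0
  - 0.0
  - -0.0
  - 0.0
  - 0.0
  - -0.0
  - 0.0
  - -0.0
  - -0.0
  - 0.0
  fc:
  - 0.0
  - -0.0
  - 0.0
  - -0.0
  - -0.0
  - -0.0
  - -0.0
  - -0.0
  - 0.0
  - 0.0
connectivity_scale:
  sc:
  - 0.0053
  - 0.0006
  fc:
  - 0.32
  - 0.03
noise_scales:
  quality_resid: auto
  connectivity_resid: 0.0
  sc_edge_sdlog: 0.0
  fc_edge_sd: 0.0
  motion_skew: 0.0
template:
  seed: 42
  n_regions: 94
  presence: deterministic
  d0_intra: 0.495
  d0_inter: 0.455
  slope: 0.036
  weight_tau: 0.35
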