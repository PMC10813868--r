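'n': 5110
seed: 1
preset: maastricht
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
  age_wmh_cor: 0.4
quality_coeffs:
  dmri:
    isnr:
    - 0.117
    - -0.071
    - -0.017
    - 0.067
    - 0.032
    - 0.004
    - -0.038
    motion:
    - 0.368
    - -0.279
    - 0.001
    - 0.028
    - 0.095
    - 0.02
    - 0.048
    mismatch:
    - 0.056
    - -0.303
    - -0.009
    - 0.093
    - -0.023
    - 0.009
    - 0.017
  fmri:
    isnr:
    - 0.17
    - -0.027
    - -0.044
    - 0.408
    - 0.096
    - -0.012
    - 0.03
    motion:
    - 0.079
    - -0.071
    - -0.01
    - 0.321
    - 0.024
    - -0.004
    - -0.016
    mismatch:
    - -0.088
    - 0.317
    - -0.003
    - -0.113
    - -0.02
    - 0.004
    - 0.013
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
  - 0.298
  - 0.522
connectivity_coeffs:
  sc:
  - -0.074
  - 0.213
  - -0.045
  - 0.109
  - 0.003
  - -0.01
  - 0.048
  - -0.12
  - -0.249
  - 0.021
  fc:
  - 0.015
  - -0.062
  - 0.014
  - -0.008
  - -0.03
  - -0.017
  - -0.027
  - -0.082
  - 0.048
  - 0.027
connectivity_scale:
  sc:
  - 0.0053
  - 0.0006
  fc:
  - 0.32
  - 0.03
noise_scales:
  quality_resid: auto
  connectivity_resid: auto
  sc_edge_sdlog: 0.4
  fc_edge_sd: 0.04
  motion_skew: 0.0
template:
  seed: 42
  n_regions: 94
  presence: stochastic
  d0_intra: 0.495
  d0_inter: 0.455
  slope: 0.036
  weight_tau: 0.35
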