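model:
  cl_ref: 0.097018021362379
  vc_ref: 3.0
  q_ref: 0.3
  vp_ref: 3.0
  ka_scig: 0.25
  ka_fscig: 0.2
  f_scig: 0.7
  f_fscig: 0.72724609375
  ksyn_ref: 0.194036042724758
  lbm_ref: 56.0
  theta_cl: 0.89453125
  theta_v: 1.0
  omega_cl: 0.25
  omega_vc: 0.25
  omega_ka: 0.3
  omega_ksyn: 0.3
regimens:
  scig:
    formulation: scig
    dose_per_kg: 0.15
    interval: 7.0
    horizon: 140.0
    first_dose_time: 0.0
  fscig:
    formulation: fscig
    dose_per_kg: 0.6
    interval: 28.0
    horizon: 140.0
    first_dose_time: 0.0
population:
  sex_prob_male: 0.5
  adult:
    age_range:
    - 18.0
    - 80.0
    height_mean:
    - 1.75
    - 1.62
    height_sd: 0.07
    bmi_median: 27.0
    bmi_gsd: 1.22
    bmi_range:
    - 15.0
    - 60.0
  bmi_strata:
    underweight:
      median: 17.5
      gsd: 1.05
    healthy:
      median: 21.5
      gsd: 1.1
    overweight:
      median: 27.300000000000001
      gsd: 1.05
    obese:
      median: 33.0
      gsd: 1.12
  pediatric:
    height_cv: 0.04
    height_curve:
      age:
      - 2.0
      - 3.0
      - 4.0
      - 5.0
      - 6.0
      - 8.0
      - 10.0
      - 12.0
      - 14.0
      - 16.0
      - 18.0
      male:
      - 0.87
      - 0.95
      - 1.02
      - 1.09
      - 1.15
      - 1.28
      - 1.38
      - 1.49
      - 1.63
      - 1.73
      - 1.76
      female:
      - 0.86
      - 0.94
      - 1.01
      - 1.08
      - 1.15
      - 1.27
      - 1.38
      - 1.51
      - 1.6
      - 1.62
      - 1.63
    bmi_curve:
      age:
      - 2.0
      - 4.0
      - 8.0
      - 12.0
      - 15.0
      - 18.0
      median:
      - 16.199999999999999
      - 15.800000000000001
      - 16.399999999999999
      - 18.199999999999999
      - 20.5
      - 21.5
    bmi_gsd: 1.15
    bmi_range:
    - 12.0
    - 40.0
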