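n_electrodes: 5
freq_range:
- 2.0
- 40.0
freq_step: 0.25
param_means:
  offset: 0.8
  exponent: 1.5
  iaf: 9.5
  alpha_level: 1.0
  alpha_width: 1.2
  theta_level: 0.4
param_sds:
  offset: 0.35
  exponent: 0.2
  iaf: 0.8
  alpha_level: 0.35
  alpha_width: 0.25
  theta_level: 0.2
effect_matrix:
  offset:
    age: -0.527882586384
    gender: -0.350528495806
    fa: 0.0
    score: 0.0
  exponent:
    age: -0.456289461623
    gender: -0.390825606814
    fa: 0.0
    score: 0.0
  iaf:
    age: 0.405622931943
    gender: -0.013831121742
    fa: 0.0
    score: 0.0
  alpha_level:
    age: 0.242913909822
    gender: -0.493219679851
    fa: 0.165404187165
    score: 0.080672561431
  alpha_width:
    age: -0.001107137228
    gender: 0.112654287684
    fa: 0.0
    score: 0.0
  theta_level:
    age: -0.044768094471
    gender: 0.313888206842
    fa: 0.0
    score: 0.0
residual_corr:
- - 1.0
  - 0.9
  - 0.0
  - 0.25
  - 0.0
  - 0.0
- - 0.9
  - 1.0
  - 0.0
  - 0.2
  - 0.0
  - 0.0
- - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 0.0
  - 0.0
- - 0.25
  - 0.2
  - 0.0
  - 1.0
  - 0.0
  - 0.0
- - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
- - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
noise_sd: 0.03
artifact_rate: 0.02
theta_center: 4.5
theta_width: 0.6
iaf_clip_eps: 0.5
age_range:
- 5.0
- 22.0
age_mean: 10.8
age_sd: 3.44
p_female: 0.357
fa_age_loading: 0.5
score_age_loading: 0.0
diagnosis_probs:
  none: 0.107
  adhd: 0.587
  other: 0.306
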