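drug: lamivudine
n_cmt: 2
theta:
  cl: 19.6
  v2: 105.0
  q: 2.97
  ka: 2.3
v3_rule: equal_v2
covariates:
- target: cl
  covariate: weight
  form: allometric
  reference: 70.0
  value: 0.75
- target: cl
  covariate: egfr
  form: power
  reference: 99.0
  value: 0.533
- target: cl
  covariate: race_black
  form: categorical
  reference: ~
  value: 0.789
- target: v2
  covariate: weight
  form: allometric
  reference: 70.0
  value: 1.0
- target: q
  covariate: weight
  form: allometric
  reference: 70.0
  value: 0.75
omega:
  names:
  - eta_cl
  - eta_v2
  - eta_ruv
  matrix:
  - - 0.0883
    - -0.0531
    - 0.0
  - - -0.0531
    - 0.158
    - 0.0
  - - 0.0
    - 0.0
    - 0.247
prop_sd: 0.359
dose: 300.0
tau: 24.0
lloq: 0.0025
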