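drug: dolutegravir
n_cmt: 1
theta:
  cl: 0.858
  v2: 16.7
  ka: 2.15
v3_rule: none
covariates:
- target: cl
  covariate: weight
  form: power
  reference: 79.0
  value: 0.427
- target: cl
  covariate: bilirubin
  form: power
  reference: 8.0
  value: -0.153
- target: cl
  covariate: ethnicity_hispanic
  form: categorical
  reference: ~
  value: 0.844
- target: v2
  covariate: weight
  form: power
  reference: 79.0
  value: 0.917
omega:
  names:
  - eta_cl
  - eta_ruv
  matrix:
  - - 0.0682
    - 0.0
  - - 0.0
    - 0.0567
prop_sd: 0.341
dose: 50.0
tau: 24.0
lloq: 0.02
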