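name: christie
intercept: -4.654
terms:
- covariate: age
  transform: identity
  coefficient: 0.019
- covariate: baseline_alc
  transform: identity
  coefficient: -0.544
- covariate: chemo
  transform: identity
  coefficient: 0.435
- covariate: rt_duration
  transform: identity
  coefficient: 0.09
- covariate: mean_heart_dose
  transform: identity
  coefficient: 0.028
- covariate: mean_lung_dose
  transform: identity
  coefficient: 0.046
- covariate: vertebrae_v20
  transform: identity
  coefficient: 0.014
interactions: []
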