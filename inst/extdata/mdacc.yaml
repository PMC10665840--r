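name: mdacc
intercept: -22.844999999999999
terms:
- covariate: age
  transform: identity
  coefficient: 0.021
- covariate: baseline_alc
  transform: identity
  coefficient: -1.019
- covariate: bmi
  transform: identity
  coefficient: 0.516
- covariate: ptv_ml
  transform: log
  coefficient: 3.579
- covariate: photons
  transform: identity
  coefficient: 0.949
interactions:
- covariate1: bmi
  transform1: identity
  covariate2: ptv_ml
  transform2: log
  coefficient: -0.086
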