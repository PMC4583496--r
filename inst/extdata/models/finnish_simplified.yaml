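# Simplified Finnish diabetes risk model — banded age, BMI and waist
# circumference plus antihypertensive medication, on the logit scale.
# PLACEHOLDER coefficients; substitute the published values for
# substantive use.
name: finnish_simplified
intercept: -5.5
link: logistic
terms:
- variable: age
  coefficient: 1.0
  transform: band
  breaks: [45.0, 55.0]
  scores: [0.0, 0.5, 0.9]
- variable: bmi
  coefficient: 1.0
  transform: band
  breaks: [25.0, 30.0]
  scores: [0.0, 0.3, 0.9]
- variable: waist_circumference
  coefficient: 1.0
  transform: band
  breaks: [94.0, 102.0]
  scores: [0.0, 0.4, 0.9]
- variable: htn_medication
  coefficient: 0.7
  transform: identity
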