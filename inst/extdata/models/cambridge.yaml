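# Cambridge diabetes risk model — structure of the published score
# (age, sex, BMI, steroid use, antihypertensive use, family history,
# smoking). Coefficients below are PLACEHOLDER values of plausible sign
# and magnitude; replace them with the exact published coefficients
# before drawing substantive conclusions.
name: cambridge
intercept: -6.3
link: logistic
terms:
- variable: gender        # 1 = female; male indicator
  coefficient: 0.9
  transform: indicator
  category: 0
- variable: age
  coefficient: 0.06
  transform: identity
- variable: bmi
  coefficient: 1.0
  transform: band
  breaks: [25.0, 27.5, 30.0]
  scores: [0.0, 0.4, 0.9, 1.4]
- variable: htn_medication
  coefficient: 1.2
  transform: identity
- variable: corticosteroids
  coefficient: 2.2
  transform: identity
- variable: fh_mother
  coefficient: 0.4
  transform: identity
- variable: fh_father
  coefficient: 0.4
  transform: identity
- variable: smoking
  coefficient: 0.8
  transform: indicator
  category: current
- variable: smoking
  coefficient: 0.3
  transform: indicator
  category: past
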