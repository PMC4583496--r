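# Rotterdam predictive model 1 — structure: age, sex, BMI bands,
# antihypertensive medication. PLACEHOLDER coefficients; substitute the
# published values for substantive use.
name: rotterdam
intercept: -6.0
link: logistic
terms:
- variable: age
  coefficient: 0.06
  transform: identity
- variable: gender        # 1 = female; male indicator
  coefficient: 0.3
  transform: indicator
  category: 0
- variable: bmi
  coefficient: 1.0
  transform: band
  breaks: [25.0, 30.0]
  scores: [0.0, 0.3, 0.8]
- variable: htn_medication
  coefficient: 0.6
  transform: identity
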