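# Kuwaiti risk model — structure: age bands, waist circumference,
# family history, antihypertensive medication. PLACEHOLDER coefficients;
# substitute the published values for substantive use.
name: kuwaiti
intercept: -5.4
link: logistic
terms:
- variable: age
  coefficient: 1.0
  transform: band
  breaks: [35.0, 45.0, 55.0]
  scores: [0.0, 0.3, 0.8, 1.2]
- variable: waist_circumference
  coefficient: 0.025
  transform: identity
- variable: fh_mother
  coefficient: 0.5
  transform: identity
- variable: fh_sister
  coefficient: 0.3
  transform: identity
- variable: htn_medication
  coefficient: 0.7
  transform: identity
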