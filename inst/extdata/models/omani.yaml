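# Omani diabetes risk model — structure: age, waist circumference, BMI,
# family history, hypertension treatment. PLACEHOLDER coefficients;
# substitute the published values for substantive use.
name: omani
intercept: -7.2
link: logistic
terms:
- variable: age
  coefficient: 0.05
  transform: identity
- variable: waist_circumference
  coefficient: 0.02
  transform: identity
- variable: bmi
  coefficient: 0.05
  transform: identity
- variable: fh_mother
  coefficient: 0.6
  transform: identity
- variable: fh_brother
  coefficient: 0.3
  transform: identity
- variable: htn_medication
  coefficient: 0.6
  transform: identity
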