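# Default cohort schema: 14 analysis variables plus the
# previously-diagnosed-diabetes exclusion flag. Binary variables are
# coded 0/1; the labels field documents what 1 means.
- name: age
  kind: continuous
  units: years
- name: gender
  kind: binary
  labels:
    female: 1
- name: bmi
  kind: continuous
  units: kg/m2
- name: waist_circumference
  kind: continuous
  units: cm
- name: sbp
  kind: continuous
  units: mmHg
- name: dbp
  kind: continuous
  units: mmHg
- name: fh_mother
  kind: binary
- name: fh_father
  kind: binary
- name: fh_sister
  kind: binary
- name: fh_brother
  kind: binary
- name: corticosteroids
  kind: binary
- name: htn_medication
  kind: binary
- name: smoking
  kind: categorical
  categories: ["current", "past", "no"]
- name: undiagnosed_diabetes
  kind: binary
- name: known_diabetes
  kind: binary
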