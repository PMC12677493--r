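- name: depressive_symptoms
  role: exposure
  family: binary
  levels:
  - 'No'
  - 'Yes'
  andersen_domain: none
- name: inpatient
  role: outcome
  family: binary
  levels:
  - 'No'
  - 'Yes'
  andersen_domain: none
- name: pain
  role: mediator
  family: binary
  levels:
  - 'No'
  - 'Yes'
  andersen_domain: need
- name: smoking
  role: mediator
  family: binary
  levels:
  - 'No'
  - 'Yes'
  andersen_domain: predisposing
- name: alcohol_use
  role: mediator
  family: binary
  levels:
  - 'No'
  - 'Yes'
  andersen_domain: predisposing
- name: disability
  role: mediator
  family: binary
  levels:
  - 'No'
  - 'Yes'
  andersen_domain: need
- name: health_status
  role: mediator
  family: ordinal
  levels:
  - Poor
  - Neutral
  - Good
  andersen_domain: need
- name: satisfaction_health
  role: mediator
  family: ordinal
  levels:
  - Dissatisfied
  - Neutral
  - Satisfied
  andersen_domain: need
- name: adl
  role: mediator
  family: ordinal
  levels:
  - No limitation
  - Mildly limited
  - Moderately limited
  - Severely limited
  andersen_domain: need
- name: chronic_disease
  role: mediator
  family: ordinal
  levels:
  - None
  - Single
  - Multiple
  andersen_domain: need
- name: gender
  role: control
  family: binary
  levels:
  - Female
  - Male
  andersen_domain: predisposing
- name: age
  role: control
  family: ordinal
  levels:
  - 60-69
  - 70-79
  - '>=80'
  andersen_domain: predisposing
- name: marital_status
  role: control
  family: binary
  levels:
  - 'No'
  - 'Yes'
  andersen_domain: predisposing
- name: ethnicity
  role: control
  family: binary
  levels:
  - Non-Han
  - Han
  andersen_domain: predisposing
- name: residence
  role: control
  family: binary
  levels:
  - Urban
  - Rural
  andersen_domain: predisposing
- name: religious_belief
  role: control
  family: binary
  levels:
  - 'No'
  - 'Yes'
  andersen_domain: predisposing
- name: work_status
  role: control
  family: binary
  levels:
  - 'No'
  - 'Yes'
  andersen_domain: predisposing
- name: education
  role: control
  family: ordinal
  levels:
  - Illiterate
  - Primary
  - Secondary
  - Higher
  andersen_domain: enabling
- name: pension
  role: control
  family: binary
  levels:
  - 'No'
  - 'Yes'
  andersen_domain: enabling
- name: satisfaction_healthcare
  role: control
  family: ordinal
  levels:
  - Dissatisfied
  - Neutral
  - Satisfied
  andersen_domain: enabling
- name: physical_examination
  role: control
  family: binary
  levels:
  - 'No'
  - 'Yes'
  andersen_domain: enabling
- name: health_insurance
  role: control
  family: binary
  levels:
  - 'No'
  - 'Yes'
  andersen_domain: enabling
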