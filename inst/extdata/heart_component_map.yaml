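# Editable HEAR/HEART component mapping from the prehospital covariate
# schema. Points per component are 0/1/2; HEART adds the troponin band.
age_breaks: [45, 65]          # age_pts: 0 below 45, 1 for 45-64, 2 for >= 65
risk_breaks: [1, 3]           # risk_pts: 0 for 0, 1 for 1-2, 2 for >= 3 factors
risk_factors:
  - hypercholesterolemia
  - hypertension
  - current_smoker
  - diabetes
  - family_history_cv
risk_forcing:                  # any of these forces risk_pts = 2
  - prior_mi
  - prior_pci
  - prior_cabg
  - cad
autonomic_symptoms:            # chest pain + any of these -> history_pts = 2
  - sym_diaphoresis
  - sym_nausea_vomiting
  - sym_syncope
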