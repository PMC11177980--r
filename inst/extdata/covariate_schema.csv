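name,group,kind
age,baseline,numeric
gender_male,baseline,binary
hypercholesterolemia,history,binary
hypertension,history,binary
current_smoker,history,binary
diabetes,history,binary
prior_mi,history,binary
angina,history,binary
prior_cabg,history,binary
prior_pci,history,binary
cad,history,binary
family_history_cv,history,binary
sym_other,symptom,binary
sym_chestpain,symptom,binary
sym_syncope,symptom,binary
sym_shortness_breath,symptom,binary
sym_diaphoresis,symptom,binary
sym_nausea_vomiting,symptom,binary
sym_palpitations,symptom,binary
sym_other_symptoms,symptom,binary
ecg_st_elevation,ecg,binary_vector_11
ecg_st_depression,ecg,binary_vector_11
ecg_t_wave_inversion,ecg,binary_vector_11
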