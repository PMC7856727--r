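condition_id,label
blood_clotting_disorders,Blood clotting disorders
syncope,Syncope
heart_failure,Heart failure
heart_block,Heart block
cardiac_arrhythmia,Cardiac arrhythmia
delirium,Delirium
parkinson_disease,Parkinson disease
dementia_cognitive_impairment,Dementia/Cognitive impairment
falls,Falls
epilepsy_seizures,Epilepsy/Seizures
behavioural_psychological_symptoms_of_dementia,Behavioural and psychological symptoms of dementia
depression,Depression
lewy_body_disease,Lewy body disease
sleep_apnea_syndrome,Sleep apnea syndrome
postural_hypotension,Postural hypotension
hypertension,Hypertension
raynaud_disease,Raynaud disease
venous_thromboembolism,Venous thromboembolism
hypokalaemia,Hypokalaemia
hyponatraemia,Hyponatraemia
hyperkalaemia,Hyperkalaemia
hypercalcaemia,Hypercalcaemia
diabetes,Diabetes
diabetic_hypoglycemia,Diabetic hypoglycemia
glaucoma,Glaucoma
chronic_constipation,Chronic constipation
chronic_kidney_disease,Chronic kidney disease
peptic_ulcer_disease,Peptic ulcer disease
lower_urinary_tract_symptoms,Lower urinary tract symptoms
urinary_retention,Urinary retention
benign_prostatic_hyperplasia,Benign prostatic hyperplasia
urinary_incontinence,Urinary incontinence
prostate_adenoma,Prostate adenoma
gout,Gout
osteoarthritis,Osteoarthritis
osteoporosis,Osteoporosis
breast_cancer,Breast cancer
chronic_obstructive_pulmonary_disease,Chronic obstructive pulmonary disease
asthma,Asthma
respiratory_failure,Respiratory failure
severe_active_liver_diseases,Severe active liver diseases
transplanted_organ_and_tissue_status,Transplanted organ and tissue status
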