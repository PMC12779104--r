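code,description,allowed_genders,age_min,age_max
185,Malignant neoplasm of prostate,male,40,124
600.0,Benign prostatic hyperplasia,male,40,124
183.0,Malignant neoplasm of ovary,female,12,124
180.9,Malignant neoplasm of cervix uteri,female,12,124
V22.2,Pregnant state incidental,female,12,56
650,Normal delivery,female,12,56
770.6,Transitory tachypnea of newborn,male|female,0,1
774.6,Unspecified fetal and neonatal jaundice,male|female,0,1
771.81,Septicemia of newborn,male|female,0,1
314.01,Attention deficit disorder with hyperactivity,male|female,1,18
493.90,Asthma unspecified,male|female,0,124
401.9,Unspecified essential hypertension,male|female,12,124
250.00,Diabetes mellitus type II without complication,male|female,12,124
414.01,Coronary atherosclerosis of native artery,male|female,30,124
331.0,Alzheimer's disease,male|female,56,124
162.9,Malignant neoplasm of bronchus and lung,male|female,19,124
486,Pneumonia organism unspecified,male|female,0,124
428.0,Congestive heart failure unspecified,male|female,12,124
038.9,Unspecified septicemia,male|female,0,124
584.9,Acute kidney failure unspecified,male|female,0,124
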