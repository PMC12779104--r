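code,description,allowed_genders,age_min,age_max
58660,Laparoscopy with lysis of adhesions of oviduct or ovary,female,12,124
58150,Total abdominal hysterectomy,female,12,124
59400,Routine obstetric care with vaginal delivery,female,12,56
55700,Biopsy of prostate,male,40,124
55866,Laparoscopic radical prostatectomy,male,40,124
54150,Circumcision with clamp,male,0,124
90460,Immunization administration through 18 years,male|female,0,18
99381,Initial preventive visit infant,male|female,0,1
99397,Periodic preventive visit 65 years and older,male|female,56,124
33533,Coronary artery bypass single arterial graft,male|female,30,124
47562,Laparoscopic cholecystectomy,male|female,12,124
45378,Diagnostic colonoscopy,male|female,19,124
71020,Radiologic examination chest two views,male|female,0,124
36415,Collection of venous blood by venipuncture,male|female,0,124
99291,Critical care first 30-74 minutes,male|female,0,124
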