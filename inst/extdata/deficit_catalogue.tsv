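name	kind	fi_s	fi_r	fi_c
On medication for arthritis	binary	1	0	0
On medication for elevated cholesterol	binary	1	0	0
On medication for hypertension	binary	1	0	0
On medication for hypothyroidism	binary	1	0	0
History of cardiovascular disease	binary	1	0	1
History of endocrine-metabolic disease	binary	1	0	1
History of head, eyes, ears, nose, and throat diseases	binary	1	0	1
History of dermatologic-connective tissue disease	binary	1	0	1
History of gastrointestinal disease	binary	1	0	1
History of hematopoietic-lymphatic disease	binary	1	0	1
History of hepatic disease	binary	1	0	1
History of malignancies	binary	1	0	1
History of musculoskeletal disease	binary	1	0	1
History of neurological (non-AD) disease	binary	1	0	1
History of psychiatric disease	binary	1	1	1
History of renal-genitourinary disease	binary	1	0	1
History of respiratory disease	binary	1	0	1
History of other diseases	binary	1	0	0
History of major surgical procedures	binary	1	0	0
FAQ, writing checks, paying bills, or balancing checkbook	ordinal	1	1	1
FAQ, assembling tax records, business affairs, or other papers	ordinal	1	1	1
FAQ, heating water, making a cup of coffee	ordinal	1	1	1
FAQ, traveling out of the neighborhood	ordinal	1	1	1
FAQ, preparing a balanced meal	ordinal	1	1	1
FAQ, paying attention to and understanding a TV program, book, or magazine	ordinal	1	1	1
FAQ, playing a game of skill such as bridge or chess	ordinal	1	1	1
FAQ, shopping alone for clothes, household	ordinal	1	1	1
NPI, agitation	binary	1	1	1
NPI, anxiety	binary	1	1	1
NPI, depression	binary	1	1	0
NPI, irritability	binary	1	1	1
NPI, sleep disturbance	binary	1	1	0
NPI, apathy	binary	1	1	1
NPI, aberrant motor behavior	binary	1	1	1
NPI, change in appetite and eating	binary	1	1	0
Auditory impairment on physical exam	binary	1	0	0
Cranial nerve abnormality on physical exam	binary	1	0	0
Abnormal finger to nose test	binary	1	0	1
Abnormal heel-knee test	binary	1	0	0
Abnormal gait on physical exam	binary	1	1	1
Motor strength deficit on physical exam	binary	1	0	0
Abnormal plantar reflex on physical exam	binary	1	0	0
Abnormal tendon reflex on physical exam	binary	1	0	0
Sensory nerve abnormality on physical exam	binary	1	0	0
Tremor on physical exam	binary	1	0	1
Vision impairment on physical exam	binary	1	0	0
Symptoms from abdomen	binary	1	0	0
Self-reported ankle swelling	binary	1	0	0
Self-reported shortness of breath	binary	1	0	1
Self-reported chest pain	binary	1	0	0
Self-reported constipation	binary	1	0	1
Self-reported cough	binary	1	0	0
Self-reported depressed mood	binary	1	1	0
Self-reported dizziness	binary	1	0	1
Self-reported drowsiness	binary	1	1	1
Self-reported dry mouth	binary	1	0	0
Self-reported low energy	binary	1	1	1
Self-reported recent fall	binary	1	0	1
Self-reported insomnia	binary	1	0	1
Self-reported life satisfaction	binary	1	0	0
Self-reported muscle pain	binary	1	0	1
Self-reported palpitations	binary	1	0	0
Self-reported urinary discomfort	binary	1	0	1
Self-reported urinary frequency	binary	1	0	0
Self-reported vision disturbance	binary	1	0	0
Blood albumin (g/dL)	continuous	1	0	0
Blood alkaline phosphatase (ALP; U/L)	continuous	1	0	0
Blood alanine aminotransferase (ALT; U/L)	continuous	1	0	0
Blood aspartate aminotransferase (AST; U/L)	continuous	1	0	0
Blood vitamin B12 (pg/mL)	continuous	1	0	0
Blood total bilirubin (mg/dL)	continuous	1	0	0
Blood calcium (mg/dL)	continuous	1	0	0
Blood cholesterol (mg/dL)	continuous	1	0	0
Blood creatinine (mg/dL)	continuous	1	0	0
Blood glucose (mg/dL)	continuous	1	0	0
Blood hematocrit (%)	continuous	1	0	0
Blood hemoglobin (g/dL)	continuous	1	0	0
Blood mean corpuscular hemoglobin (MCH; pg)	continuous	1	0	0
Blood mean corpuscular volume (MCV; fL)	continuous	1	0	0
Blood neutrophil count (10^3/uL)	continuous	1	1	0
Blood total protein (g/dL)	continuous	1	0	0
Blood red blood cell count (RBC; 10^6/uL)	continuous	1	1	0
Blood triglycerides (mg/dL)	continuous	1	0	0
Blood urea nitrogen (BUN; mg/dL)	continuous	1	0	0
Blood uric acid (mg/dL)	continuous	1	0	0
Body mass index (BMI)	continuous	1	0	0
Diastolic blood pressure (mmHg)	continuous	1	0	1
Heart rate (count)	continuous	1	0	0
Mean arterial pressure (mmHg)	continuous	1	0	0
Pulse pressure (mmHg)	continuous	1	1	0
Systolic blood pressure (mmHg)	continuous	1	0	1
Number of medications (polypharmacy)	continuous	1	1	0
Elevated geriatric depression scale (GDS) score	binary	1	1	0
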