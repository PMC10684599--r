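code	phecode	phecode_label
E11.0	250.2	Type 2 diabetes
E11.2	250.2	Type 2 diabetes
E11.3	250.2	Type 2 diabetes
E11.9	250.2	Type 2 diabetes
E10.9	250.1	Type 1 diabetes
H36.0	250.7	Diabetic retinopathy
I10	401.1	Essential hypertension
I20.0	411.1	Unstable angina
I20.8	411.1	Unstable angina
I20.9	411.1	Unstable angina
I21.9	411.2	Myocardial infarction
I25.1	411.4	Coronary atherosclerosis
I48	427.2	Atrial fibrillation
I50.0	428.2	Heart failure
I50.9	428.2	Heart failure
J40	496.0	Chronic bronchitis
J41.0	496.0	Chronic bronchitis
J42	496.0	Chronic bronchitis
J44.9	496.1	COPD
J45.9	495.0	Asthma
K21.9	530.1	GERD
K80.2	574.1	Cholelithiasis
M16.9	740.2	Osteoarthritis of hip
M17.9	740.1	Osteoarthritis of knee
M81.0	743.1	Osteoporosis
M81.9	743.1	Osteoporosis
N18.3	585.3	Chronic kidney disease stage 3
N18.9	585.0	Chronic kidney disease
N39.1	791.0	Albuminuria
E78.0	272.1	Hypercholesterolemia
F32.9	296.2	Major depressive disorder
G47.3	327.3	Sleep apnea
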