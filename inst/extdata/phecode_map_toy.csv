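icd,vocabulary,phecode,label,exclusion_min,exclusion_max,sex
401.1,ICD9CM,401.1,Essential hypertension,401,405,none
401.9,ICD9CM,401.1,Essential hypertension,401,405,none
I10,ICD10,401.1,Essential hypertension,401,405,none
402.0,ICD9CM,401.2,Hypertensive heart disease,401,405,none
I11.9,ICD10,401.2,Hypertensive heart disease,401,405,none
410.0,ICD9CM,411.2,Myocardial infarction,410,414,none
410.9,ICD9CM,411.2,Myocardial infarction,410,414,none
I21.9,ICD10,411.2,Myocardial infarction,410,414,none
413.9,ICD9CM,411.8,Angina pectoris,410,414,none
I20.9,ICD10,411.8,Angina pectoris,410,414,none
244.9,ICD9CM,244,Hypothyroidism,240,246,none
E03.9,ICD10,244,Hypothyroidism,240,246,none
250.00,ICD9CM,250.2,Type 2 diabetes,249,250.7,none
E11.9,ICD10,250.2,Type 2 diabetes,249,250.7,none
185,ICD9CM,185,Cancer of prostate,185,187,male
C61,ICD10,185,Cancer of prostate,185,187,male
618.0,ICD9CM,618.2,Uterine prolapse,618,618.9,female
N81.9,ICD10,618.2,Uterine prolapse,618,618.9,female
714.0,ICD9CM,714.1,Rheumatoid arthritis,714,714.9,none
M06.9,ICD10,714.1,Rheumatoid arthritis,714,714.9,none
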