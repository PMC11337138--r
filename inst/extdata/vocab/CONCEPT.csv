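"concept_id","concept_name","domain_id","vocabulary_id","concept_code","standard_concept"
0,"No matching concept","Metadata","None","No matching concept",""
8507,"MALE","Gender","Gender","M","S"
8532,"FEMALE","Gender","Gender","F","S"
38004247,"Ambulatory Primary Care Clinic/Center","Visit","Visit","APCC","S"
9202,"Outpatient Visit","Visit","Visit","OP","S"
32817,"EHR","Type","Type Concept","OMOP4976890","S"
32856,"Lab","Type","Type Concept","OMOP4976929","S"
44818701,"From physical examination","Type","Type Concept","44818701","S"
38004446,"General Practice","Provider","Provider","GP","S"
800000001,"Reason for consultation note","Type","Note Type","NT01","S"
800000002,"Interview note","Type","Note Type","NT02","S"
800000003,"Diagnosis note","Type","Note Type","NT03","S"
800000004,"Referral note","Type","Note Type","NT04","S"
800000005,"Vaccination note","Type","Note Type","NT05","S"
800000006,"Supplementary information note","Type","Note Type","NT06","S"
800000007,"Medical history note","Type","Note Type","NT07","S"
800000008,"Clinical report from external physician","Type","Note Type","NT08","S"
45500001,"Type 2 diabetes mellitus","Condition","ICD10","E11","S"
45500002,"Essential hypertension","Condition","ICD10","I10","S"
45500003,"Asthma","Condition","ICD10","J45","S"
45500004,"Disorders of lipoprotein metabolism","Condition","ICD10","E78","S"
45500005,"Depressive episode","Condition","ICD10","F32","S"
45500006,"Dorsalgia","Condition","ICD10","M54","S"
45500007,"Gastro-oesophageal reflux disease","Condition","ICD10","K21","S"
45500008,"Hypothyroidism","Condition","ICD10","E03","S"
45500009,"Obesity","Condition","ICD10","E66","S"
45500010,"Atrial fibrillation and flutter","Condition","ICD10","I48","S"
45500011,"Chronic kidney disease","Condition","ICD10","N18","S"
45500012,"Chronic obstructive pulmonary disease","Condition","ICD10","J44","S"
45500013,"Migraine","Condition","ICD10","G43","S"
45500014,"Atopic dermatitis","Condition","ICD10","L20","S"
46000001,"Body weight","Measurement","SNOMED","27113001","S"
46000002,"Body height","Measurement","SNOMED","50373000","S"
46000003,"Systolic blood pressure","Measurement","SNOMED","271649006","S"
46000004,"Diastolic blood pressure","Measurement","SNOMED","271650006","S"
46000005,"Heart rate","Measurement","SNOMED","364075005","S"
46000006,"Body mass index","Measurement","SNOMED","60621009","S"
47000001,"Potassium","Measurement","LOINC","2823-3","S"
47000002,"Sodium","Measurement","LOINC","2951-2","S"
47000003,"Creatinine","Measurement","LOINC","2160-0","S"
47000004,"C-reactive protein","Measurement","LOINC","1988-5","S"
47000005,"Hemoglobin","Measurement","LOINC","718-7","S"
47000006,"Glucose","Measurement","LOINC","2345-7","S"
47000007,"Thyrotropin","Measurement","LOINC","3016-3","S"
47000008,"Alanine aminotransferase","Measurement","LOINC","1742-6","S"
47000009,"Cholesterol","Measurement","LOINC","2093-3","S"
47000010,"Hemoglobin A1c","Measurement","LOINC","4548-4","S"
47000011,"Urea nitrogen","Measurement","LOINC","3094-0","S"
47000012,"Neutrophils","Measurement","LOINC","751-8","S"
48000001,"unit mmol/L","Unit","UCUM","mmol/L","S"
48000002,"unit umol/L","Unit","UCUM","umol/L","S"
48000003,"unit mg/L","Unit","UCUM","mg/L","S"
48000004,"unit g/dL","Unit","UCUM","g/dL","S"
48000005,"unit g/L","Unit","UCUM","g/L","S"
48000006,"unit kg","Unit","UCUM","kg","S"
48000007,"unit cm","Unit","UCUM","cm","S"
48000008,"unit mmHg","Unit","UCUM","mmHg","S"
48000009,"unit /min","Unit","UCUM","/min","S"
48000010,"unit kg/m2","Unit","UCUM","kg/m2","S"
48000011,"unit %","Unit","UCUM","%","S"
49000001,"paracetamol","Drug","ATC","N02BE01",""
49000002,"amoxicillin","Drug","ATC","J01CA04",""
49000003,"lisinopril","Drug","ATC","C09AA03",""
49000004,"metformin","Drug","ATC","A10BA02",""
49000005,"simvastatin","Drug","ATC","C10AA01",""
49000006,"amlodipine","Drug","ATC","C08CA01",""
49000007,"levothyroxine","Drug","ATC","H03AA01",""
49000008,"ibuprofen","Drug","ATC","M01AE01",""
49000009,"omeprazole","Drug","ATC","A02BC01",""
49000010,"atenolol","Drug","ATC","C07AB03",""
49000011,"salbutamol","Drug","ATC","R03AC02",""
49000012,"amoxicillin and beta-lactamase inhibitor","Drug","ATC","J01CR02",""
49000013,"lorazepam","Drug","ATC","N05BA06",""
50000001,"acetaminophen 500 MG Oral Tablet","Drug","RxNorm","RX00001","S"
50000002,"amoxicillin 500 MG Oral Capsule","Drug","RxNorm","RX00002","S"
50000003,"lisinopril 10 MG Oral Tablet","Drug","RxNorm","RX00003","S"
50000004,"metformin 500 MG Oral Tablet","Drug","RxNorm","RX00004","S"
50000005,"simvastatin 20 MG Oral Tablet","Drug","RxNorm","RX00005","S"
50000006,"amlodipine 5 MG Oral Tablet","Drug","RxNorm","RX00006","S"
50000007,"levothyroxine 0.05 MG Oral Tablet","Drug","RxNorm","RX00007","S"
50000008,"ibuprofen 400 MG Oral Tablet","Drug","RxNorm","RX00008","S"
50000009,"omeprazole 20 MG Oral Capsule","Drug","RxNorm","RX00009","S"
50000010,"atenolol 50 MG Oral Tablet","Drug","RxNorm","RX00010","S"
50000011,"albuterol 0.09 MG/ACTUAT Inhaler","Drug","RxNorm","RX00011","S"
50000012,"amoxicillin 500 MG / clavulanate 125 MG Oral Tablet","Drug","RxNorm","RX00012","S"
51000001,"acetaminophen","Drug","RxNorm Ingredient","IN00001","S"
51000002,"amoxicillin","Drug","RxNorm Ingredient","IN00002","S"
51000003,"lisinopril","Drug","RxNorm Ingredient","IN00003","S"
51000004,"metformin","Drug","RxNorm Ingredient","IN00004","S"
51000005,"simvastatin","Drug","RxNorm Ingredient","IN00005","S"
51000006,"amlodipine","Drug","RxNorm Ingredient","IN00006","S"
51000007,"levothyroxine","Drug","RxNorm Ingredient","IN00007","S"
51000008,"ibuprofen","Drug","RxNorm Ingredient","IN00008","S"
51000009,"omeprazole","Drug","RxNorm Ingredient","IN00009","S"
51000010,"atenolol","Drug","RxNorm Ingredient","IN00010","S"
51000011,"albuterol","Drug","RxNorm Ingredient","IN00011","S"
51000012,"clavulanate","Drug","RxNorm Ingredient","IN00012","S"
52000001,"paracetamol 500mg cp","Drug","CIP","3400930000011",""
52000002,"amoxicilline 500mg gel","Drug","CIP","3400930000028",""
52000003,"lisinopril 10mg cp","Drug","CIP","3400930000035",""
52000004,"metformine 500mg cp","Drug","CIP","3400930000042",""
52000005,"simvastatine 20mg cp","Drug","CIP","3400930000059",""
52000006,"amlodipine 5mg cp","Drug","CIP","3400930000066",""
52000007,"levothyroxine 50ug cp","Drug","CIP","3400930000073",""
52000008,"ibuprofene 400mg cp","Drug","CIP","3400930000080",""
52000009,"amoxicilline acide clavulanique 500mg cp","Drug","CIP","3400930000097",""
52000010,"omeprazole 20mg gel","Drug","CIP","3400930000104",""
52000011,"atenolol 50mg cp","Drug","CIP","3400930000111",""
52000012,"salbutamol aerosol","Drug","CIP","3400930000128",""
52000013,"paracetamol 1g cp","Drug","CIP","3400930000135",""
52000014,"metformine 850mg cp","Drug","CIP","3400930000142",""
52000015,"amoxicilline 250mg gel","Drug","CIP","3400930000159",""
52000016,"ibuprofene 200mg cp","Drug","CIP","3400930000166",""
52000017,"simvastatine 40mg cp","Drug","CIP","3400930000173",""
52000018,"lorazepam 1mg cp","Drug","CIP","3400930000180",""
52000019,"produit sans lien atc","Drug","CIP","3400930000197",""
52000020,"autre produit sans lien atc","Drug","CIP","3400930000204",""
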