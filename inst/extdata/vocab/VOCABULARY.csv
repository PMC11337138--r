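"vocabulary_id","vocabulary_name"
"None","Vocabulary: None"
"Gender","Vocabulary: Gender"
"Visit","Vocabulary: Visit"
"Type Concept","Vocabulary: Type Concept"
"Provider","Vocabulary: Provider"
"Note Type","Vocabulary: Note Type"
"ICD10","Vocabulary: ICD10"
"SNOMED","Vocabulary: SNOMED"
"LOINC","Vocabulary: LOINC"
"UCUM","Vocabulary: UCUM"
"ATC","Vocabulary: ATC"
"RxNorm","Vocabulary: RxNorm"
"RxNorm Ingredient","Vocabulary: RxNorm Ingredient"
"CIP","Vocabulary: CIP"
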