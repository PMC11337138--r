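# Patient export XML schema, version 1.0

One XML document per patient. The root element carries the schema version;
parsers reject documents declaring an unknown version. All dates are ISO-8601
calendar dates (`YYYY-MM-DD`); there are no times. Patient and consultation
identifiers are opaque strings, unique across the export.

```
<patient-export schema-version="1.0">
  <patient id="pat-000123">
    <demographics sex="F|M" year-of-birth="1962" town="Wattrelos"
                  country="France"/>          <!-- town optional -->
    <registration physician="DR002" date="2014-03-05"/>
    <death date="2020-11-02"/>                <!-- optional -->

    <medical-history>                          <!-- optional -->
      <item coded="true" icd10="E11" date="2015-01-10"/>
      <item coded="false" date="2015-01-10">diabetique depuis 2004</item>
    </medical-history>

    <consultations>                            <!-- four steps per visit -->
      <consultation id="pat-000123-c0001" date="2015-03-01">
        <reason>...</reason>                   <!-- step 1: free text -->
        <interview>...</interview>             <!-- step 2: free text,
                                                    optional -->
        <examination>                          <!-- step 3: structured,
                                                    optional -->
          <biometric variable="Poids" value="72.5" unit="kg"/>
        </examination>
        <outcome>                              <!-- step 4 -->
          <diagnosis>...</diagnosis>           <!-- optional free text -->
          <prescription cip="3400930000011" days-supply="30"
                        refills="2" quantity="1"/>   <!-- 0..n -->
          <referral>...</referral>             <!-- optional free text -->
          <vaccination>...</vaccination>       <!-- optional free text -->
          <supplementary>...</supplementary>   <!-- optional free text -->
        </outcome>
      </consultation>
    </consultations>

    <lab-results>
      <result-set laboratory="LAB1" date="2015-04-01"
                  consultation-ref="pat-000123-c0001"> <!-- ref optional -->
        <result variable="Potassium" value="4.10" unit="mmol/L"/>
      </result-set>
    </lab-results>

    <clinical-reports>                         <!-- optional -->
      <report date="2015-05-02">Compte rendu ...</report>
    </clinical-reports>

    <addresses>
      <address line="12 rue des Lilas" town="Wattrelos"
               postal-code="59150" country="France"/>
    </addresses>
  </patient>
</patient-export>
```

Notes.

- Laboratory `variable`/`unit` strings are laboratory-specific: the same
  analyte appears under different spellings and units depending on the
  reporting laboratory (e.g. `Creatinine` in `umol/L` vs `create` in
  `mg/L`). This heterogeneity is intentional; the semantic-mapping layer
  resolves it.
- Biometric `variable` labels are free-typed physician labels (French by
  default) inside structured fields.
- Prescription drugs are identified by CIP codes only; `days-supply`,
  `refills` and `quantity` are optional dosage attributes.
- A `result-set` may reference the consultation it was ordered from; the
  reference may be absent.
- Each consultation step is explicitly delimited by its own element; a
  consultation never spans multiple documents.
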