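# Shared fixtures, generated once per test run and reused across files.

.fixtures <- new.env(parent = emptyenv())

# a modest defect-free export with its full ETL result
shared_pipeline <- function() {
  if (is.null(.fixtures$pipe)) {
    cfg <- generator_config(n_patients = 30, mean_visits_per_patient = 6,
                            mean_lab_panels_per_patient = 4,
                            death_rate = 0.1, seed = 202)
    g <- generate_export(cfg)
    store <- load_vocabulary_fixture()
    res <- etl_pipeline(g$export$dir, store = store)
    .fixtures$pipe <- list(cfg = cfg, export = g$export,
                           manifest = g$manifest, store = store, res = res)
  }
  .fixtures$pipe
}

# minimal hand-written patient document exercising the documented schema
write_tiny_document <- function(dir = tempfile("doc-")) {
  dir.create(dir)
  path <- file.path(dir, "pat-000001.xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<patient-export schema-version="1.0">',
    '  <patient id="pat-000001">',
    '    <demographics sex="F" year-of-birth="1962" town="Wattrelos" country="France"/>',
    '    <registration physician="DR001" date="2014-03-05"/>',
    '    <consultations>',
    '      <consultation id="pat-000001-c0001" date="2015-03-01">',
    '        <reason>Fievre</reason>',
    '        <interview>Examen clinique sans particularite</interview>',
    '        <examination>',
    '          <biometric variable="Poids" value="72.5" unit="kg"/>',
    '          <biometric variable="TA systolique" value="128.0" unit="mmHg"/>',
    '        </examination>',
    '        <outcome>',
    '          <diagnosis>Syndrome viral</diagnosis>',
    '          <prescription cip="3400930000011" days-supply="7" refills="0" quantity="1"/>',
    '        </outcome>',
    '      </consultation>',
    '    </consultations>',
    '    <lab-results>',
    '      <result-set laboratory="LAB1" date="2015-03-08" consultation-ref="pat-000001-c0001">',
    '        <result variable="Potassium" value="4.10" unit="mmol/L"/>',
    '      </result-set>',
    '    </lab-results>',
    '    <addresses>',
    '      <address line="12 rue des Lilas" town="Wattrelos" postal-code="59150" country="France"/>',
    '    </addresses>',
    '  </patient>',
    '</patient-export>'), path)
  path
}

# make a staging_store from plain tables (for focused unit tests)
as_staging <- function(...) {
  tabs <- omopetl:::staging_templates()
  args <- list(...)
  for (nm in names(args)) {
    df <- args[[nm]]
    for (col in setdiff(names(tabs[[nm]]), names(df))) df[[col]] <- NA
    tabs[[nm]] <- df[, names(tabs[[nm]])]
  }
  structure(tabs, class = "staging_store")
}
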