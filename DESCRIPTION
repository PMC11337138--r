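Package: omopetl
Title: Primary Care EHR to OMOP CDM Extract-Transform-Load Toolkit
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for standardizing primary care electronic health record
    exports into the OMOP Common Data Model (CDM) v5.4. Provides a synthetic
    per-patient XML export generator with a ground-truth manifest, staging
    extraction and profiling, four-level semantic mapping of local
    vocabularies to OHDSI standard vocabularies (label normalization,
    two-hop CIP-to-ATC-to-RxNorm drug mapping, dual-annotator reconciliation
    with Cohen's kappa, coverage reporting), structural mapping into a CDM
    subset with derived OBSERVATION_PERIOD and DRUG_ERA tables, a
    schema-validating warehouse loader, Kahn-framework data-quality checks
    (Conformance, Completeness, Plausibility), source-versus-warehouse
    validation queries, and dashboard data export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
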