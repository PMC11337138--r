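test_that("a clean synthetic build fails no quality check", {
  p <- shared_pipeline()
  qr <- run_checks(p$res$cdm, ranges = default_plausibility_ranges(p$store))
  expect_identical(sum(qr$status == "fail"), 0L)
  s <- summarize_checks(qr)
  expect_identical(sum(s$failed), 0L)
  expect_identical(sum(s$checks), nrow(qr))
})

test_that("an empty warehouse passes all checks vacuously", {
  store <- create_cdm_store()
  qr <- run_checks(store)
  expect_true(all(qr$status == "pass"))
  expect_true(all(qr$total == 0))
})

test_that("each injected defect kind triggers its Kahn check with exact counts", {
  cfg <- generator_config(n_patients = 40, mean_visits_per_patient = 6,
                          mean_lab_panels_per_patient = 4,
                          death_rate = 0.3, seed = 7)
  g <- generate_export(cfg)
  inj <- inject_defects(g$export, g$manifest,
                        list(event_after_death = 3, value_out_of_range = 5,
                             birth_year_implausible = 2,
                             dangling_visit_reference = 2,
                             missing_required_field = 2), seed = 3)
  store <- load_vocabulary_fixture()
  # no transform-side filtering, no load-side enforcement: the quality layer
  # judges the warehouse content as loaded
  res <- etl_pipeline(g$export$dir, store = store, enforce = FALSE)
  qr <- run_checks(res$cdm, ranges = default_plausibility_ranges(store))
  failed <- qr$check_id[qr$status == "fail"]
  viol <- stats::setNames(qr$violations, qr$check_id)
  tr <- inj$manifest$truth

  # dangling_visit_reference: every member row of a ghosted result set
  expect_true("conf_measurement_visit_fk" %in% failed)
  expect_identical(viol[["conf_measurement_visit_fk"]],
                   sum(grepl("GHOST", tr$lab_results$consultation_ref)))

  # missing_required_field (sex removed) -> gender completeness
  expect_true("comp_person_gender" %in% failed)
  expect_identical(viol[["comp_person_gender"]], 2L)

  # birth_year_implausible -> birth-year plausibility
  expect_true("plaus_birth_year" %in% failed)
  expect_identical(viol[["plaus_birth_year"]], 2L)

  # value_out_of_range -> measurement-range plausibility
  expect_true("plaus_measurement_range" %in% failed)
  expect_identical(viol[["plaus_measurement_range"]], 5L)

  # event_after_death: the re-dated visits plus their attached records
  expect_true("plaus_event_after_death" %in% failed)
  d <- merge(tr$consultations,
             tr$patients[, c("patient_id", "death_date")])
  moved <- d$consultation_id[!is.na(d$death_date) &
                               as.Date(d$date) > as.Date(d$death_date)]
  expected <- length(moved) +
    sum(tr$prescriptions$consultation_id %in% moved) +
    sum(tr$biometrics$consultation_id %in% moved) +
    sum(res$staging$notes$consultation_id %in% moved)
  expect_identical(viol[["plaus_event_after_death"]], as.integer(expected))

  # one failing check per defect kind, and nothing in the clean categories
  # beyond the known date-horizon consequence of moving visits past death
  extra <- setdiff(failed,
                   c("conf_measurement_visit_fk", "comp_person_gender",
                     "plaus_birth_year", "plaus_measurement_range",
                     "plaus_event_after_death",
                     "plaus_event_before_extraction"))
  expect_length(extra, 0)
})

test_that("a concept from the wrong domain is flagged by conformance", {
  p <- shared_pipeline()
  tabs <- p$res$cdm$tables
  drug_concept <- tabs$CONCEPT$concept_id[
    tabs$CONCEPT$domain_id == "Drug" &
      tabs$CONCEPT$standard_concept == "S"][1]
  tabs$MEASUREMENT$measurement_concept_id[1] <- drug_concept
  qr <- run_checks(tabs, ranges = default_plausibility_ranges(p$store))
  dom <- qr[qr$check_id == "conf_measurement_domain", ]
  expect_identical(dom$status, "fail")
  expect_identical(dom$violations, 1L)
})

test_that("category summaries partition the results exactly", {
  p <- shared_pipeline()
  qr <- run_checks(p$res$cdm, ranges = default_plausibility_ranges(p$store))
  s <- summarize_checks(qr)
  expect_identical(sum(s$checks),
                   length(default_quality_registry()))
  expect_identical(s$checks, s$passed + s$failed)
  expect_setequal(s$category,
                  c("Conformance", "Completeness", "Plausibility"))
})

test_that("value distributions report exact order statistics", {
  tabs <- list(
    MEASUREMENT = data.frame(measurement_id = 1:3, person_id = 1L,
                             measurement_concept_id = 42,
                             value_as_number = c(3.5, 4.0, 4.5)),
    CONCEPT = data.frame(concept_id = 42, concept_name = "Potassium"))
  d <- value_distribution(tabs, 42)
  expect_identical(d$median, 4.0)
  expect_identical(d$min, 3.5); expect_identical(d$max, 4.5)
  single <- tabs
  single$MEASUREMENT <- single$MEASUREMENT[1, ]
  d1 <- value_distribution(single, 42)
  expect_identical(d1$min, d1$median)
  expect_identical(d1$median, d1$max)
  expect_error(value_distribution(tabs, 999),
               class = "omopetl_lookup_error")
})

test_that("the generated potassium distribution recovers its parameters", {
  cfg <- generator_config(
    n_patients = 100, mean_visits_per_patient = 0,
    mean_lab_panels_per_patient = 60,
    lab_vocabulary_variants = list(
      potassium = data.frame(label = "Potassium", unit = "mmol/L",
                             mean = 4.2, sd = 0.4)),
    seed = 314)
  cfg$mean_history_items <- 0; cfg$mean_clinical_reports <- 0
  g <- generate_export(cfg)
  res <- etl_pipeline(g$export$dir)
  pota <- res$store$concept$concept_id[
    res$store$concept$concept_name == "Potassium" &
      res$store$concept$standard_concept == "S"]
  d <- value_distribution(res$cdm, pota,
                          default_plausibility_ranges(res$store))
  expect_gt(d$n, 5000)
  expect_lt(abs(d$median - 4.2), 0.05)
  expect_identical(d$out_of_range, 0L)
})
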