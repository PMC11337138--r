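make_demo_staging <- function() {
  as_staging(
    patients = data.frame(
      patient_id = c("pa", "pb", "pc"), sex = c("M", "F", "F"),
      year_of_birth = c("1970", "1985", "1990"),
      town = "Wattrelos", country = "France",
      physician_id = c("DR1", "DR1", "DR2"),
      registration_date = "2015-01-01", file = "f"),
    addresses = data.frame(
      patient_id = c("pa", "pb", "pc"),
      line = c("1 rue A", "1 rue A", "2 rue B"), town = "Wattrelos",
      postal_code = "59150", country = "France"),
    deaths = data.frame(patient_id = "pb", date = "2020-05-01"))
}

annotated_ledger_for <- function(staging, store) {
  annotate_ledger(build_ledger(staging, store), store)
}

test_that("demographics build persons, deduplicated locations and deaths", {
  store <- load_vocabulary_fixture()
  staging <- make_demo_staging()
  ledger <- annotated_ledger_for(staging, store)
  demo <- build_demographics(staging, ledger)
  expect_identical(nrow(demo$PERSON), 3L)
  expect_identical(nrow(demo$LOCATION), 2L)   # two patients share an address
  expect_identical(nrow(demo$CARE_SITE), 1L)
  expect_identical(nrow(demo$DEATH), 1L)
  expect_identical(demo$DEATH$person_id, unname(demo$person_map["pb"]))
  # sex mapped through the ledger to the standard gender concepts
  expect_setequal(unique(demo$PERSON$gender_concept_id), c(8507, 8532))
  # person ids are dense sequential integers
  expect_identical(demo$PERSON$person_id, 1:3)
})

test_that("an unmapped sex yields gender concept 0 with a warning, not a failure", {
  store <- load_vocabulary_fixture()
  staging <- make_demo_staging()
  staging$patients$sex[2] <- NA
  ledger <- annotated_ledger_for(staging, store)
  demo <- build_demographics(staging, ledger)
  expect_identical(demo$PERSON$gender_concept_id[2], 0)
  expect_match(demo$warnings, "sex", all = FALSE)
})

test_that("builds degrade gracefully with no deaths, no kept rows, empty notes", {
  store <- load_vocabulary_fixture()
  staging <- make_demo_staging()
  staging$deaths <- staging$deaths[0, ]
  ledger <- annotated_ledger_for(staging, store)
  demo <- build_demographics(staging, ledger)
  expect_identical(nrow(demo$DEATH), 0L)
  # every measurement rejected still yields an exact rejection log
  labs <- data.frame(patient_id = "pa", laboratory = "LAB1",
                     date = "2015-06-01", consultation_ref = NA_character_,
                     variable = "Potassium", value = c("900", "901"),
                     unit = "mmol/L")
  st2 <- make_demo_staging(); st2$lab_results <- labs
  ledger2 <- annotated_ledger_for(st2, store)
  out <- build_measurements(NULL, labs, ledger2,
                            default_plausibility_ranges(store),
                            person_map = c(pa = 1L), visit_map = integer(0))
  expect_null(out$MEASUREMENT)
  expect_identical(nrow(out$rejections), 2L)
  # all-empty note texts are all skipped
  notes <- data.frame(patient_id = "pa", consultation_id = NA_character_,
                      date = "2015-06-01", class = "reason", text = c("", " "))
  nb <- build_notes(notes, store, person_map = c(pa = 1L),
                    visit_map = integer(0))
  expect_null(nb$NOTE)
  expect_identical(nrow(nb$skipped), 2L)
  # a full pipeline over a no-death export loads clean
  cfg <- generator_config(n_patients = 4, mean_visits_per_patient = 2,
                          death_rate = 0, seed = 3)
  g <- generate_export(cfg)
  res <- etl_pipeline(g$export$dir)
  expect_true(all(res$load_report$rejected == 0))
})

test_that("visits are one row per consultation with duplicates collapsed", {
  person_map <- c(pa = 1L, pb = 2L)
  cons <- data.frame(
    consultation_id = c("c1", "c2", "c3", "c4", "c5", "c5"),
    patient_id = c("pa", "pa", "pa", "pb", "pb", "pb"),
    date = "2016-02-03", date_valid = TRUE)
  out <- build_visits(cons, person_map)
  expect_identical(nrow(out$VISIT_OCCURRENCE), 5L)
  expect_true(all(out$VISIT_OCCURRENCE$visit_concept_id == 38004247))
  expect_identical(out$VISIT_OCCURRENCE$visit_start_date,
                   out$VISIT_OCCURRENCE$visit_end_date)
  bad <- data.frame(consultation_id = "cx", patient_id = "ghost",
                    date = "2016-01-01", date_valid = TRUE)
  expect_error(build_visits(bad, person_map),
               class = "omopetl_integrity_error")
})

test_that("measurement building filters outliers with exact conservation", {
  store <- load_vocabulary_fixture()
  n <- 100L
  staging <- as_staging(
    patients = data.frame(patient_id = "p1", sex = "F",
                          year_of_birth = "1970", town = "X", country = "FR",
                          physician_id = "DR1",
                          registration_date = "2015-01-01", file = "f"),
    lab_results = data.frame(
      patient_id = "p1", laboratory = "LAB1", date = "2015-06-01",
      consultation_ref = NA_character_, variable = "Potassium",
      value = as.character(c(rep(4.1, 88), rep(410, 12))),
      unit = "mmol/L"))
  ledger <- annotated_ledger_for(staging, store)
  ranges <- default_plausibility_ranges(store)
  out <- build_measurements(staging$biometrics, staging$lab_results, ledger,
                            ranges, person_map = c(p1 = 1L),
                            visit_map = integer(0))
  expect_identical(nrow(out$MEASUREMENT), 88L)
  expect_identical(nrow(out$rejections), 12L)
  expect_true(all(out$rejections$reason == "out of range"))
  expect_identical(nrow(out$MEASUREMENT) + nrow(out$rejections), n)
  expect_true(all(out$MEASUREMENT$measurement_type_concept_id == 32856))
  expect_true(all(out$MEASUREMENT$measurement_source_type_id == "laboratory"))
  # a non-numeric value is logged, not fatal
  staging$lab_results$value[1] <- "n/a"
  out2 <- build_measurements(staging$biometrics, staging$lab_results, ledger,
                             ranges, person_map = c(p1 = 1L),
                             visit_map = integer(0))
  expect_true("non-numeric value" %in% out2$rejections$reason)
})

test_that("unmapped measurement labels keep concept 0 and the raw source value", {
  store <- load_vocabulary_fixture()
  staging <- as_staging(
    patients = data.frame(patient_id = "p1", sex = "F",
                          year_of_birth = "1970", town = "X", country = "FR",
                          physician_id = "DR1",
                          registration_date = "2015-01-01", file = "f"),
    lab_results = data.frame(
      patient_id = "p1", laboratory = "LAB1", date = "2015-06-01",
      consultation_ref = NA_character_, variable = "dosage mysterieux",
      value = "1.0", unit = "mmol/L"))
  ledger <- annotated_ledger_for(staging, store)
  out <- build_measurements(staging$biometrics, staging$lab_results, ledger,
                            NULL, person_map = c(p1 = 1L),
                            visit_map = integer(0))
  expect_identical(out$MEASUREMENT$measurement_concept_id, 0)
  expect_identical(out$MEASUREMENT$measurement_source_value,
                   "dosage mysterieux")
  # the raw label still has a registered local source concept
  expect_gt(out$MEASUREMENT$measurement_source_concept_id, 2e9)
})

test_that("drug exposures carry the two-hop mapping or concept 0 with source value", {
  store <- load_vocabulary_fixture()
  cips <- store$concept$concept_code[store$concept$vocabulary_id == "CIP"]
  staging <- as_staging(
    patients = data.frame(patient_id = "p1", sex = "F",
                          year_of_birth = "1970", town = "X", country = "FR",
                          physician_id = "DR1",
                          registration_date = "2015-01-01", file = "f"),
    consultations = data.frame(consultation_id = "c1", patient_id = "p1",
                               date = "2015-06-01", date_valid = TRUE),
    prescriptions = data.frame(
      patient_id = "p1", consultation_id = "c1", date = "2015-06-01",
      cip = cips, days_supply = "30", refills = "1", quantity = "2"))
  ledger <- annotated_ledger_for(staging, store)
  rx <- build_drug_exposures(staging$prescriptions, ledger,
                             person_map = c(p1 = 1L), visit_map = c(c1 = 1L))
  expect_identical(nrow(rx), 20L)
  expect_identical(sum(rx$drug_concept_id != 0), 17L)
  unmapped <- rx[rx$drug_concept_id == 0, ]
  expect_true(all(nzchar(unmapped$drug_source_value)))
  # exposure end = start + days_supply - 1
  expect_identical(unique(as.numeric(rx$drug_exposure_end_date -
                                       rx$drug_exposure_start_date)), 29)
})

test_that("notes carry provenance concepts, skip empty text, and keep routing", {
  store <- load_vocabulary_fixture()
  notes <- data.frame(
    patient_id = "p1", consultation_id = c("c1", "c1", "c1", NA, NA),
    date = "2015-06-01",
    class = c("reason", "interview", "diagnosis", "history",
              "clinical_report"),
    text = c("Fievre", "RAS", "Syndrome viral", "diabetique depuis 2004",
             ""))
  out <- build_notes(notes, store, person_map = c(p1 = 1L),
                     visit_map = c(c1 = 7L))
  expect_identical(nrow(out$NOTE), 4L)        # empty text skipped
  expect_identical(nrow(out$skipped), 1L)
  expect_identical(length(unique(out$NOTE$note_class_concept_id)), 4L)
  expect_true(all(out$NOTE$note_class_concept_id > 0))
  expect_identical(out$NOTE$visit_occurrence_id, c(7L, 7L, 7L, NA_integer_))
})

test_that("only coded histories become observations; invalid codes get concept 0", {
  store <- load_vocabulary_fixture()
  staging <- as_staging(
    patients = data.frame(patient_id = "p1", sex = "F",
                          year_of_birth = "1970", town = "X", country = "FR",
                          physician_id = "DR1",
                          registration_date = "2015-01-01", file = "f"),
    histories = data.frame(
      patient_id = "p1", coded = c(TRUE, TRUE, FALSE),
      icd10 = c("E11", "not-a-code", NA),
      text = c(NA, NA, "diabetique depuis 2004"), date = "2015-06-01"))
  ledger <- annotated_ledger_for(staging, store)
  obs <- build_observations(staging$histories, ledger,
                            person_map = c(p1 = 1L))
  expect_identical(nrow(obs), 2L)             # the free-text item is not here
  e11 <- obs[obs$observation_source_value == "E11", ]
  expect_gt(e11$observation_concept_id, 0)
  bad <- obs[obs$observation_source_value == "not-a-code", ]
  expect_identical(bad$observation_concept_id, 0)
})

test_that("observation periods span each person's event dates exactly", {
  ev <- data.frame(person_id = c(1L, 1L, 1L, 3L),
                   date = as.Date(c("2015-03-01", "2017-11-20", "2019-06-30",
                                    "2018-01-01")))
  out <- derive_observation_periods(ev)
  expect_identical(nrow(out), 2L)             # person 2 has no events
  p1 <- out[out$person_id == 1, ]
  expect_identical(p1$observation_period_start_date, as.Date("2015-03-01"))
  expect_identical(p1$observation_period_end_date, as.Date("2019-06-30"))
})

test_that("drug era derivation merges by the persistence window as specified", {
  store <- load_vocabulary_fixture()
  # two exposures 15 days apart: one era at window 30, two at window 10
  w30 <- derive_eras_for_stream(store, starts = c(0, 24),
                                ends = c(9, 35), window = 30)
  expect_identical(nrow(w30), 1L)
  expect_identical(w30$start, 0); expect_identical(w30$end, 35)
  expect_identical(w30$count, 2L)
  w10 <- derive_eras_for_stream(store, starts = c(0, 24),
                                ends = c(9, 35), window = 10)
  expect_identical(nrow(w10), 2L)

  # a combination product yields one era per ingredient
  combo <- map_drug("3400930000097", store)
  exposures <- data.frame(
    drug_exposure_id = 1L, person_id = 1L,
    drug_concept_id = combo$rxnorm_concept_id,
    drug_exposure_start_date = as.Date("2020-01-01"),
    drug_exposure_end_date = as.Date("2020-01-07"))
  eras <- derive_drug_eras(exposures, store)$DRUG_ERA
  expect_identical(nrow(eras), 2L)
  expect_identical(length(unique(eras$drug_concept_id)), 2L)

  # an exposure ending before it starts is excluded and logged
  backwards <- exposures
  backwards$drug_exposure_end_date <- as.Date("2019-12-01")
  res <- derive_drug_eras(backwards, store)
  expect_null(res$DRUG_ERA)
  expect_identical(nrow(res$excluded), 1L)
})

test_that("era derivation agrees with the brute-force interval-union oracle", {
  store <- load_vocabulary_fixture()
  set.seed(11)
  for (trial in 1:100) {
    n <- sample(1:50, 1)
    starts <- sort(sample(0:400, n, replace = TRUE))
    ends <- starts + sample(0:30, n, replace = TRUE)
    for (w in c(0, 1, 30, 365)) {
      got <- derive_eras_for_stream(store, starts, ends, w)
      want <- brute_force_eras(starts, ends, w)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$count, want$count)
    }
  }
})

test_that("a full build is referentially closed and pseudonymized", {
  p <- shared_pipeline()
  tabs <- p$res$cdm$tables
  schema <- cdm_schema()
  for (tab in names(schema)) {
    df <- tabs[[tab]]
    if (is.null(df) || !nrow(df)) next
    for (fk_col in names(schema[[tab]]$fks)) {
      target <- schema[[tab]]$fks[[fk_col]]
      vals <- df[[fk_col]]
      expect_true(all(is.na(vals) |
                        vals %in% tabs[[target[1]]][[target[2]]]),
                  label = sprintf("%s.%s resolves", tab, fk_col))
    }
  }
  # no source patient identifier outside *_source_value columns
  src_ids <- p$res$staging$patients$patient_id
  for (tab in intersect(names(tabs),
                        c("PERSON", "VISIT_OCCURRENCE", "MEASUREMENT",
                          "DRUG_EXPOSURE", "NOTE", "OBSERVATION"))) {
    df <- tabs[[tab]]
    plain <- df[, !grepl("source_value", names(df)), drop = FALSE]
    for (cn in names(plain))
      if (is.character(plain[[cn]]))
        expect_false(any(plain[[cn]] %in% src_ids),
                     label = sprintf("%s.%s is pseudonymized", tab, cn))
  }
  expect_identical(tabs$PERSON$person_id, seq_len(nrow(tabs$PERSON)))
})

test_that("the transform is deterministic given identical staging and ledger", {
  p <- shared_pipeline()
  store2 <- load_vocabulary_fixture()
  staging2 <- extract_all(p$export$dir)
  ledger2 <- annotate_ledger(build_ledger(staging2, store2), store2)
  built_a <- build_cdm(staging2, ledger2, store2)
  built_b <- build_cdm(staging2, ledger2, store2)
  expect_identical(built_a$tables, built_b$tables)
})
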