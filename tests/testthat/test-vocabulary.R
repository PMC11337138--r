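test_that("the bundled vocabulary fixture loads clean and is well-formed", {
  store <- load_vocabulary_fixture()
  expect_gt(nrow(store$concept), 100)
  expect_gt(nrow(store$concept_relationship), 30)
  # all bundled ids are in the standard range; the local range starts empty
  expect_true(all(store$concept$concept_id <= 2e9))
  expect_identical(sum(store$concept$vocabulary_id == "CIP"), 20L)
})

test_that("fixture loading validates sizes and referential integrity", {
  dir <- tempfile(); dir.create(dir)
  concept <- data.frame(
    concept_id = 1:10, concept_name = paste0("c", 1:10),
    domain_id = "Measurement", vocabulary_id = "LOINC",
    concept_code = paste0("L", 1:10),
    standard_concept = "S")
  rel <- data.frame(concept_id_1 = 1:4, concept_id_2 = 5:8,
                    relationship_id = "Maps to")
  vocab <- data.frame(vocabulary_id = "LOINC", vocabulary_name = "LOINC")
  write.csv(concept, file.path(dir, "CONCEPT.csv"), row.names = FALSE)
  write.csv(rel, file.path(dir, "CONCEPT_RELATIONSHIP.csv"),
            row.names = FALSE)
  write.csv(vocab, file.path(dir, "VOCABULARY.csv"), row.names = FALSE)
  store <- load_vocabulary_fixture(dir)
  expect_identical(nrow(store$concept), 10L)
  expect_identical(nrow(store$concept_relationship), 4L)
  # a relationship referencing an absent concept is rejected, naming it
  rel_bad <- rbind(rel, data.frame(concept_id_1 = 1, concept_id_2 = 999,
                                   relationship_id = "Maps to"))
  write.csv(rel_bad, file.path(dir, "CONCEPT_RELATIONSHIP.csv"),
            row.names = FALSE)
  expect_error(load_vocabulary_fixture(dir), "999",
               class = "omopetl_integrity_error")
})

test_that("label normalization follows the documented rule sequence", {
  expect_identical(normalize_label("CRP"), "c-reactive protein")
  expect_identical(normalize_label("  creatinine "), "creatinine")
  expect_identical(
    normalize_label("3. Potassium (mmol/L):", abbreviations = character(0),
                    stopwords = c("of", "to", "an")),
    "potassium mmol l")
  expect_identical(normalize_label("taux de creatinine"), "creatinine")
})

test_that("normalization is idempotent on fixture labels and random noise", {
  store <- load_vocabulary_fixture()
  labels <- c(store$concept$concept_name, "K+", "Na+", "TA systolique",
              "3) CRP  (mg/L):", "Glycemie a jeun", "12. Hb--",
              "Poids (kg)", "create")
  set.seed(42)
  noise <- replicate(50, paste(sample(c(letters, LETTERS, 0:9, "(", ")",
                                        ".", "/", "-", " ", ":"),
                                      sample(3:25, 1), replace = TRUE),
                               collapse = ""))
  for (x in c(labels, noise)) {
    once <- normalize_label(x)
    expect_identical(normalize_label(once), once)
  }
})

test_that("difficulty levels follow the four-level scheme", {
  store <- load_vocabulary_fixture()
  # an ICD-10 code present as a standard concept: level 1
  expect_identical(classify_difficulty(
    list(label = "E11", code = "E11", vocabulary = "ICD10"), store), 1L)
  # an ATC code whose ATC -> RxNorm link pre-exists: level 2
  expect_identical(classify_difficulty(
    list(label = "metformin", code = "A10BA02", vocabulary = "ATC"),
    store), 2L)
  # a structured but unmapped label: level 3
  expect_identical(classify_difficulty(
    list(label = "vitesse de sedimentation"), store), 3L)
  # free text: level 4
  expect_identical(classify_difficulty(
    list(label = "douleur abdominale", structured = FALSE), store), 4L)
})

test_that("the two-hop drug mapping records both hops and failure reasons", {
  store <- load_vocabulary_fixture()
  full <- map_drug("3400930000011", store)
  expect_identical(full$status, "mapped")
  expect_false(is.na(full$atc_concept_id))
  expect_false(is.na(full$rxnorm_concept_id))
  # ATC parent without an ATC -> RxNorm link
  hop2 <- map_drug("3400930000180", store)
  expect_identical(hop2$status, "unmapped")
  expect_identical(hop2$reason, "missing second hop")
  expect_false(is.na(hop2$atc_concept_id))
  # no ATC parent at all
  hop1 <- map_drug("3400930000197", store)
  expect_identical(hop1$reason, "missing first hop")
  expect_error(map_drug("12ab", store), class = "omopetl_input_error")
  # exhaustive traversal over the fixture's 20 CIP codes: 17 complete chains
  cips <- store$concept$concept_code[store$concept$vocabulary_id == "CIP"]
  mapped <- vapply(cips, function(cc) map_drug(cc, store)$status,
                   character(1))
  expect_identical(sum(mapped == "mapped"), 17L)
  expect_identical(coverage_percent(sum(mapped == "mapped"), length(cips)),
                   85.0)
})

test_that("local concept registration allocates ids above two billion, idempotently", {
  dir <- tempfile(); dir.create(dir)
  concept <- data.frame(concept_id = 1, concept_name = "c",
                        domain_id = "Measurement", vocabulary_id = "LOINC",
                        concept_code = "L1", standard_concept = "S")
  write.csv(concept, file.path(dir, "CONCEPT.csv"), row.names = FALSE)
  write.csv(data.frame(concept_id_1 = numeric(0), concept_id_2 = numeric(0),
                       relationship_id = character(0)),
            file.path(dir, "CONCEPT_RELATIONSHIP.csv"), row.names = FALSE)
  write.csv(data.frame(vocabulary_id = "LOINC", vocabulary_name = "LOINC"),
            file.path(dir, "VOCABULARY.csv"), row.names = FALSE)
  store <- load_vocabulary_fixture(dir)
  first <- register_local_concept(store, "vitesse de sedimentation",
                                  "Weda-lab", "Measurement")
  expect_identical(first$concept_id, 2000000001)
  again <- register_local_concept(store, "vitesse de sedimentation",
                                  "Weda-lab", "Measurement")
  expect_identical(again$concept_id, first$concept_id)
  ids <- vapply(1:50, function(i)
    register_local_concept(store, paste("concept", i), "Weda-lab",
                           "Measurement")$concept_id, numeric(1))
  expect_identical(anyDuplicated(ids), 0L)
  expect_true(all(ids > 2e9))
  expect_error(register_local_concept(store, "", "Weda-lab", "Measurement"),
               class = "omopetl_input_error")
})

test_that("consensus recording handles agreement, adjudication and pending states", {
  store <- load_vocabulary_fixture()
  staging <- as_staging(
    patients = data.frame(patient_id = "p1", sex = "F",
                          year_of_birth = "1970", town = "X", country = "FR",
                          physician_id = "DR1",
                          registration_date = "2015-01-01", file = "f"),
    lab_results = data.frame(patient_id = "p1", laboratory = "LAB1",
                             date = "2015-01-02", consultation_ref = NA,
                             variable = c("Potassium", "mystere"),
                             value = c("4.1", "9"), unit = "mmol/L"))
  ledger <- build_ledger(staging, store)
  pota <- ledger$item_id[ledger$raw_label == "Potassium"]
  myst <- ledger$item_id[ledger$raw_label == "mystere"]
  c1 <- store$concept$concept_id[store$concept$concept_name == "Potassium"]
  c2 <- store$concept$concept_id[store$concept$concept_name == "Sodium"]

  ledger <- record_consensus(ledger, pota, c1, c1, store = store)
  row <- ledger[ledger$item_id == pota, ]
  expect_identical(row$consensus_concept_id, c1)
  expect_false(row$adjudicated)
  # the consensus appended a Maps to from the local concept to the standard
  rels <- store$concept_relationship
  expect_true(any(rels$concept_id_1 == row$local_concept_id &
                    rels$concept_id_2 == c1 &
                    rels$relationship_id == "Maps to"))

  ledger <- record_consensus(ledger, myst, c1, c2, adjudicator = c2,
                             store = store)
  row <- ledger[ledger$item_id == myst, ]
  expect_identical(row$consensus_concept_id, c2)
  expect_true(row$adjudicated)

  ledger2 <- record_consensus(ledger, myst, c1, c2)
  expect_true(ledger2[ledger2$item_id == myst, "pending"])
  expect_error(record_consensus(ledger, myst, NA, c2),
               class = "omopetl_input_error")
})

test_that("a 152-item reconciliation with 37 disagreements leaves 37 adjudicated flags", {
  store <- load_vocabulary_fixture()
  loinc <- store$concept$concept_id[store$concept$vocabulary_id == "LOINC"]
  staging <- as_staging(
    patients = data.frame(patient_id = "p1", sex = "F",
                          year_of_birth = "1970", town = "X", country = "FR",
                          physician_id = "DR1",
                          registration_date = "2015-01-01", file = "f"),
    lab_results = data.frame(patient_id = "p1", laboratory = "LAB1",
                             date = "2015-01-02", consultation_ref = NA,
                             variable = sprintf("analyte %03d", 1:152),
                             value = "1", unit = "mmol/L"))
  ledger <- build_ledger(staging, store)
  items <- ledger$item_id[ledger$feature == "laboratory"]
  expect_length(items, 152)
  set.seed(1)
  disagree <- sample(152, 37)
  for (i in seq_along(items)) {
    a <- loinc[1 + (i %% 4)]
    b <- if (i %in% disagree) loinc[6] else a
    ledger <- record_consensus(ledger, items[i], a, b, adjudicator = a,
                               store = store)
  }
  expect_identical(sum(ledger$adjudicated), 37L)
  expect_identical(coverage_percent(37, 152), 24.3)
})

test_that("Cohen's kappa matches hand computations and the contingency oracle", {
  # perfect agreement over several categories
  expect_identical(cohen_kappa(c("x", "y", "z"), c("x", "y", "z"))$kappa, 1)
  # symmetric total disagreement: p_o = 0, kappa = -1
  k <- cohen_kappa(c("x", "x", "y", "y"), c("y", "y", "x", "x"))
  expect_identical(k$p_o, 0)
  expect_identical(k$kappa, -1)
  expect_identical(k$n_disagreements, 4L)
  expect_error(cohen_kappa("a", c("a", "b")), class = "omopetl_input_error")

  # randomized paired annotations against the brute-force contingency table
  # and against an independent library implementation
  set.seed(99)
  for (trial in 1:200) {
    n <- sample(1:200, 1)
    k_cats <- sample(2:6, 1)
    a <- sample(letters[1:k_cats], n, replace = TRUE)
    b <- sample(letters[1:k_cats], n, replace = TRUE)
    got <- cohen_kappa(a, b)$kappa
    want <- kappa_from_contingency(a, b)
    expect_equal(got, want, tolerance = 1e-12)
  }
  a <- sample(letters[1:3], 500, replace = TRUE)
  b <- sample(letters[1:3], 500, replace = TRUE)
  ca <- e1071::classAgreement(table(factor(a, levels = letters[1:3]),
                                    factor(b, levels = letters[1:3])))
  expect_equal(cohen_kappa(a, b)$kappa, ca$kappa, tolerance = 1e-12)
})

test_that("kappa sits near zero for independent annotators", {
  set.seed(7)
  a <- sample(c("x", "y", "z"), 10000, replace = TRUE)
  b <- sample(c("x", "y", "z"), 10000, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)$kappa), 0.05)
})

test_that("coverage percentages round half away from zero to one decimal", {
  expect_identical(coverage_percent(183, 200), 91.5)
  expect_identical(coverage_percent(0, 50), 0.0)
  expect_true(is.na(coverage_percent(0, 0)))
  # half-away-from-zero, where banker's rounding would differ
  expect_identical(round_half_up(0.25, 1), 0.3)
  expect_identical(round(0.25, 1), 0.2)  # base R reference point
  expect_identical(round_half_up(-0.25, 1), -0.3)
})

test_that("coverage reporting aggregates the ledger and stays monotonic", {
  p <- shared_pipeline()
  rep <- coverage_report(p$res$ledger)
  expect_true(all(rep$mapped_concepts_n <= rep$mapped_concepts_N,
                  na.rm = TRUE))
  lvl4 <- rep[rep$difficulty_level == 4, ]
  expect_true(all(is.na(lvl4$mapped_concepts_pct)))
  # adding a mapping never decreases any coverage percentage
  ledger <- p$res$ledger
  unmapped <- which(ledger$difficulty_level == 3 &
                      is.na(ledger$consensus_concept_id))
  if (length(unmapped)) {
    std <- p$store$concept$concept_id[
      p$store$concept$standard_concept == "S"][1]
    ledger2 <- record_consensus(ledger, ledger$item_id[unmapped[1]],
                                std, std)
    rep2 <- coverage_report(ledger2)
    ok <- !is.na(rep$mapped_concepts_pct)
    expect_true(all(rep2$mapped_concepts_pct[ok] >=
                      rep$mapped_concepts_pct[ok]))
  }
})

test_that("fuzzy suggestions propose close standard concepts but never auto-accept", {
  store <- load_vocabulary_fixture()
  sug <- suggest_concepts("Potasium", store, "LOINC",
                          min_similarity = 0.8)
  expect_identical(sug$concept_name[1], "Potassium")
  none <- suggest_concepts("zzzz", store, "LOINC")
  expect_identical(nrow(none), 0L)
})
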