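vocab_tables <- function() {
  store <- load_vocabulary_fixture()
  list(VOCABULARY = store$vocabulary, CONCEPT = store$concept,
       CONCEPT_RELATIONSHIP = store$concept_relationship)
}

test_that("schema creation materializes all 15 tables and round-trips", {
  store <- create_cdm_store()
  expect_length(store$tables, 15L)
  expect_setequal(names(store$tables), names(cdm_schema()))
  # introspection oracle: the materialized tables match the declaration
  seen <- introspect_cdm_store(store)
  for (tab in names(cdm_schema())) {
    def <- cdm_schema()[[tab]]
    want <- vapply(def$columns, `[[`, character(1), "type")
    names(want) <- vapply(def$columns, `[[`, character(1), "name")
    expect_identical(seen[[tab]], want)
  }
})

test_that("creating a warehouse over an existing one is an explicit error", {
  path <- tempfile("cdm-")
  create_cdm_store(path = path)
  expect_error(create_cdm_store(path = path), "already exists",
               class = "omopetl_schema_error")
})

test_that("valid rows load and foreign-key violations are rejected with reasons", {
  store <- create_cdm_store()
  rep0 <- load_cdm(store, vocab_tables())
  expect_true(all(rep0$rejected == 0))
  persons <- data.frame(person_id = 1:3, gender_concept_id = 8507,
                        year_of_birth = 1970L, person_source_value = "x")
  visits <- data.frame(
    visit_occurrence_id = 1:100,
    person_id = c(rep(1:3, length.out = 99), 99L),
    visit_concept_id = 38004247,
    visit_start_date = as.Date("2015-01-01"),
    visit_end_date = as.Date("2015-01-01"))
  rep <- load_cdm(store, list(PERSON = persons, VISIT_OCCURRENCE = visits))
  vrow <- rep[rep$table == "VISIT_OCCURRENCE", ]
  expect_identical(vrow$attempted, 100L)
  expect_identical(vrow$loaded, 99L)
  expect_identical(vrow$rejected, 1L)
  rej <- attr(rep, "rejections")$VISIT_OCCURRENCE
  expect_match(rej$reason, "foreign key person_id -> PERSON", fixed = TRUE)
  expect_identical(vrow$attempted, vrow$loaded + vrow$rejected)
})

test_that("duplicate keys, missing required fields and bad ordering are caught", {
  store <- create_cdm_store()
  expect_error(load_cdm(store, list(PERSON = data.frame(
    person_id = 1L, gender_concept_id = 8507))),
    class = "omopetl_input_error")  # vocabulary not loaded yet
  load_cdm(store, vocab_tables())
  persons <- data.frame(person_id = c(1L, 1L, NA), gender_concept_id = 8507)
  rep <- load_cdm(store, list(PERSON = persons))
  expect_identical(rep$loaded, 1L)
  expect_identical(rep$rejected, 2L)
  reasons <- attr(rep, "rejections")$PERSON$reason
  expect_true(any(grepl("duplicate primary key", reasons)))
  expect_true(any(grepl("required column", reasons)))
  expect_error(load_cdm(store, list(NOT_A_TABLE = data.frame(x = 1))),
               class = "omopetl_input_error")
})

test_that("a full synthetic build loads with counts equal to the transform output", {
  p <- shared_pipeline()
  rep <- p$res$load_report
  for (tab in rep$table) {
    built <- p$res$cdm$tables[[tab]]
    expect_identical(rep$loaded[rep$table == tab], nrow(built))
  }
  expect_true(all(rep$rejected == 0))
  expect_true(all(rep$attempted == rep$loaded + rep$rejected))
})

test_that("the pre-load validator agrees with a relational database's constraints", {
  # independent constraint engine: sqlite3 via the system python, with
  # primary/foreign keys enforced
  set.seed(5)
  persons <- data.frame(person_id = c(1L, 2L, 3L, 3L),
                        gender_concept_id = 8507)
  visits <- data.frame(
    visit_occurrence_id = c(1L, 2L, 2L, 4L, 5L),
    person_id = c(1L, 2L, 3L, 42L, NA),
    visit_concept_id = 38004247,
    visit_start_date = as.Date("2015-01-01"),
    visit_end_date = as.Date("2015-01-01"))

  store <- create_cdm_store()
  load_cdm(store, vocab_tables())
  rep <- load_cdm(store, list(PERSON = persons, VISIT_OCCURRENCE = visits))

  person_lit <- paste0("[", paste(sprintf("(%d,)", persons$person_id),
                                  collapse = ","), "]")
  visit_lit <- paste0("[", paste(sprintf(
    "(%d,%s,'2015-01-01')", visits$visit_occurrence_id,
    ifelse(is.na(visits$person_id), "None", visits$person_id)),
    collapse = ","), "]")
  py <- sprintf('
import sqlite3
con = sqlite3.connect(":memory:")
con.execute("PRAGMA foreign_keys = ON")
con.execute("CREATE TABLE person (person_id INTEGER PRIMARY KEY)")
con.execute("""CREATE TABLE visit (visit_occurrence_id INTEGER PRIMARY KEY,
  person_id INTEGER NOT NULL REFERENCES person(person_id),
  visit_start_date TEXT)""")
def try_rows(sql, rows):
    bad = 0
    for r in rows:
        try:
            con.execute(sql, r)
        except sqlite3.Error:
            bad += 1
    return bad
pb = try_rows("INSERT INTO person VALUES (?)", %s)
vb = try_rows("INSERT INTO visit VALUES (?,?,?)", %s)
print(pb, vb)
', person_lit, visit_lit)
  out <- system2("python", "-", stdout = TRUE, input = py)
  counts <- as.integer(strsplit(trimws(out[length(out)]), " ")[[1]])
  expect_identical(rep$rejected[rep$table == "PERSON"], counts[1])
  expect_identical(rep$rejected[rep$table == "VISIT_OCCURRENCE"], counts[2])
})

test_that("a file-backed store persists one CSV per table", {
  path <- tempfile("cdm-")
  store <- create_cdm_store(path = path)
  load_cdm(store, vocab_tables())
  write_cdm_store(store)
  files <- list.files(path, pattern = "\\.csv$")
  expect_length(files, 15L)
  reread <- utils::read.csv(file.path(path, "CONCEPT.csv"))
  expect_identical(nrow(reread), nrow(store$tables$CONCEPT))
})
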