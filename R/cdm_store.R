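# OMOP CDM v5.4 subset schema and a schema-validating, file-backed warehouse.
# Fifteen tables: twelve clinical/administrative plus the three vocabulary
# tables. Loading enforces required columns, primary-key uniqueness and
# foreign-key integrity, itemizes rejected rows, and reports per-table
# volumes and computing time.

col <- function(name, type, required = FALSE)
  list(name = name, type = type, required = required)

#' The OMOP CDM v5.4 subset schema definition
#'
#' Per table: columns (name, type, required flag), primary key and foreign
#' keys. `measurement_source_type_id` is an added provenance column
#' distinguishing the two measurement source tables (laboratory data vs
#' biometrics).
#'
#' @return a `schema_definition`: named list of table definitions in load
#'   order (vocabulary tables first).
#' @export
cdm_schema <- function() {
  tabs <- list(
    VOCABULARY = list(
      columns = list(col("vocabulary_id", "character", TRUE),
                     col("vocabulary_name", "character")),
      pk = "vocabulary_id", fks = list()),
    CONCEPT = list(
      columns = list(col("concept_id", "numeric", TRUE),
                     col("concept_name", "character", TRUE),
                     col("domain_id", "character", TRUE),
                     col("vocabulary_id", "character", TRUE),
                     col("concept_code", "character"),
                     col("standard_concept", "character")),
      pk = "concept_id",
      fks = list(vocabulary_id = c("VOCABULARY", "vocabulary_id"))),
    CONCEPT_RELATIONSHIP = list(
      columns = list(col("concept_id_1", "numeric", TRUE),
                     col("concept_id_2", "numeric", TRUE),
                     col("relationship_id", "character", TRUE)),
      pk = c("concept_id_1", "concept_id_2", "relationship_id"),
      fks = list(concept_id_1 = c("CONCEPT", "concept_id"),
                 concept_id_2 = c("CONCEPT", "concept_id"))),
    LOCATION = list(
      columns = list(col("location_id", "integer", TRUE),
                     col("address_1", "character"), col("city", "character"),
                     col("zip", "character"),
                     col("country_source_value", "character")),
      pk = "location_id", fks = list()),
    CARE_SITE = list(
      columns = list(col("care_site_id", "integer", TRUE),
                     col("care_site_name", "character"),
                     col("place_of_service_concept_id", "numeric"),
                     col("location_id", "integer"),
                     col("care_site_source_value", "character")),
      pk = "care_site_id",
      fks = list(location_id = c("LOCATION", "location_id"))),
    PROVIDER = list(
      columns = list(col("provider_id", "integer", TRUE),
                     col("specialty_concept_id", "numeric"),
                     col("care_site_id", "integer"),
                     col("provider_source_value", "character")),
      pk = "provider_id",
      fks = list(care_site_id = c("CARE_SITE", "care_site_id"))),
    PERSON = list(
      columns = list(col("person_id", "integer", TRUE),
                     col("gender_concept_id", "numeric", TRUE),
                     col("year_of_birth", "integer"),
                     col("race_concept_id", "numeric"),
                     col("ethnicity_concept_id", "numeric"),
                     col("location_id", "integer"),
                     col("provider_id", "integer"),
                     col("care_site_id", "integer"),
                     col("person_source_value", "character"),
                     col("gender_source_value", "character")),
      pk = "person_id",
      fks = list(location_id = c("LOCATION", "location_id"),
                 provider_id = c("PROVIDER", "provider_id"),
                 care_site_id = c("CARE_SITE", "care_site_id"))),
    DEATH = list(
      columns = list(col("person_id", "integer", TRUE),
                     col("death_date", "date", TRUE),
                     col("death_type_concept_id", "numeric")),
      pk = "person_id",
      fks = list(person_id = c("PERSON", "person_id"))),
    OBSERVATION_PERIOD = list(
      columns = list(col("observation_period_id", "integer", TRUE),
                     col("person_id", "integer", TRUE),
                     col("observation_period_start_date", "date", TRUE),
                     col("observation_period_end_date", "date", TRUE),
                     col("period_type_concept_id", "numeric")),
      pk = "observation_period_id",
      fks = list(person_id = c("PERSON", "person_id"))),
    VISIT_OCCURRENCE = list(
      columns = list(col("visit_occurrence_id", "integer", TRUE),
                     col("person_id", "integer", TRUE),
                     col("visit_concept_id", "numeric", TRUE),
                     col("visit_start_date", "date", TRUE),
                     col("visit_end_date", "date", TRUE),
                     col("visit_type_concept_id", "numeric"),
                     col("provider_id", "integer"),
                     col("care_site_id", "integer"),
                     col("visit_source_value", "character")),
      pk = "visit_occurrence_id",
      fks = list(person_id = c("PERSON", "person_id"),
                 provider_id = c("PROVIDER", "provider_id"),
                 care_site_id = c("CARE_SITE", "care_site_id"))),
    MEASUREMENT = list(
      columns = list(col("measurement_id", "integer", TRUE),
                     col("person_id", "integer", TRUE),
                     col("measurement_concept_id", "numeric", TRUE),
                     col("measurement_date", "date", TRUE),
                     col("measurement_type_concept_id", "numeric"),
                     col("value_as_number", "numeric"),
                     col("unit_concept_id", "numeric"),
                     col("visit_occurrence_id", "integer"),
                     col("measurement_source_value", "character"),
                     col("measurement_source_concept_id", "numeric"),
                     col("unit_source_value", "character"),
                     col("measurement_source_type_id", "character")),
      pk = "measurement_id",
      fks = list(person_id = c("PERSON", "person_id"),
                 visit_occurrence_id = c("VISIT_OCCURRENCE",
                                         "visit_occurrence_id"))),
    DRUG_EXPOSURE = list(
      columns = list(col("drug_exposure_id", "integer", TRUE),
                     col("person_id", "integer", TRUE),
                     col("drug_concept_id", "numeric", TRUE),
                     col("drug_exposure_start_date", "date", TRUE),
                     col("drug_exposure_end_date", "date", TRUE),
                     col("drug_type_concept_id", "numeric"),
                     col("refills", "integer"),
                     col("quantity", "numeric"),
                     col("days_supply", "integer"),
                     col("visit_occurrence_id", "integer"),
                     col("drug_source_value", "character"),
                     col("drug_source_concept_id", "numeric")),
      pk = "drug_exposure_id",
      fks = list(person_id = c("PERSON", "person_id"),
                 visit_occurrence_id = c("VISIT_OCCURRENCE",
                                         "visit_occurrence_id"))),
    NOTE = list(
      columns = list(col("note_id", "integer", TRUE),
                     col("person_id", "integer", TRUE),
                     col("note_date", "date"),
                     col("note_type_concept_id", "numeric"),
                     col("note_class_concept_id", "numeric"),
                     col("note_title", "character"),
                     col("note_text", "character", TRUE),
                     col("encoding_concept_id", "numeric"),
                     col("language_concept_id", "numeric"),
                     col("visit_occurrence_id", "integer")),
      pk = "note_id",
      fks = list(person_id = c("PERSON", "person_id"),
                 visit_occurrence_id = c("VISIT_OCCURRENCE",
                                         "visit_occurrence_id"))),
    OBSERVATION = list(
      columns = list(col("observation_id", "integer", TRUE),
                     col("person_id", "integer", TRUE),
                     col("observation_concept_id", "numeric", TRUE),
                     col("observation_date", "date", TRUE),
                     col("observation_type_concept_id", "numeric"),
                     col("value_as_string", "character"),
                     col("visit_occurrence_id", "integer"),
                     col("observation_source_value", "character"),
                     col("observation_source_concept_id", "numeric")),
      pk = "observation_id",
      fks = list(person_id = c("PERSON", "person_id"),
                 visit_occurrence_id = c("VISIT_OCCURRENCE",
                                         "visit_occurrence_id"))),
    DRUG_ERA = list(
      columns = list(col("drug_era_id", "integer", TRUE),
                     col("person_id", "integer", TRUE),
                     col("drug_concept_id", "numeric", TRUE),
                     col("drug_era_start_date", "date", TRUE),
                     col("drug_era_end_date", "date", TRUE),
                     col("drug_exposure_count", "integer"),
                     col("gap_days", "integer")),
      pk = "drug_era_id",
      fks = list(person_id = c("PERSON", "person_id")))
  )
  structure(tabs, class = "schema_definition")
}

CLINICAL_TABLES <- c("LOCATION", "CARE_SITE", "PROVIDER", "PERSON", "DEATH",
                     "OBSERVATION_PERIOD", "VISIT_OCCURRENCE", "MEASUREMENT",
                     "DRUG_EXPOSURE", "NOTE", "OBSERVATION", "DRUG_ERA")
VOCAB_TABLES <- c("VOCABULARY", "CONCEPT", "CONCEPT_RELATIONSHIP")

empty_table <- function(def) {
  cols <- lapply(def$columns, function(cc) switch(cc$type,
    integer = integer(0), numeric = numeric(0), date = as.Date(character(0)),
    character = character(0)))
  names(cols) <- vapply(def$columns, `[[`, character(1), "name")
  as.data.frame(cols)
}

#' Create an empty warehouse with the CDM subset schema
#'
#' Materializes all 15 tables, empty and typed. With a `path`, the store is
#' file-backed: tables are persisted as one CSV per table by
#' [write_cdm_store()], and creating a second store over a non-empty
#' directory is an explicit error (no silent clobbering).
#'
#' @param path optional directory for persistence.
#' @return a `cdm_store`.
#' @export
create_cdm_store <- function(path = NULL) {
  schema <- cdm_schema()
  if (!is.null(path)) {
    if (dir.exists(path) &&
        length(list.files(path, all.files = TRUE, no.. = TRUE)))
      etl_stop("schema", "a warehouse already exists at '%s'", path)
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    writeLines("omopetl cdm v5.4 subset", file.path(path, ".cdm-schema"))
  }
  env <- new.env(parent = emptyenv())
  env$schema <- schema
  env$tables <- lapply(schema, empty_table)
  env$path <- path
  class(env) <- "cdm_store"
  env
}

#' Introspect the applied schema of a store
#'
#' Reads column names and types back from the materialized tables (not from
#' the stored definition), for round-trip comparison against [cdm_schema()].
#'
#' @param store a `cdm_store`.
#' @return named list: per table, a named character vector column -> type.
#' @export
introspect_cdm_store <- function(store) {
  lapply(store$tables, function(df)
    vapply(df, function(v) {
      if (inherits(v, "Date")) "date"
      else if (is.integer(v)) "integer"
      else if (is.numeric(v)) "numeric"
      else "character"
    }, character(1)))
}

#' @export
print.cdm_store <- function(x, ...) {
  cat("<cdm_store (OMOP CDM v5.4 subset)>\n")
  for (nm in names(x$tables))
    cat(sprintf("  %-22s %8d rows\n", nm, nrow(x$tables[[nm]])))
  invisible(x)
}

coerce_column <- function(v, type) {
  switch(type,
    integer = as.integer(v),
    numeric = as.numeric(v),
    date = if (inherits(v, "Date")) v else as_iso_date(as.character(v)),
    character = as.character(v))
}

# validate one table's candidate rows against the schema and current store
# content; returns list(ok_rows, rejects = data.frame(row, reason))
validate_rows <- function(store, table, rows) {
  def <- store$schema[[table]]
  cols <- vapply(def$columns, `[[`, character(1), "name")
  missing_cols <- setdiff(cols, names(rows))
  for (mc in missing_cols) rows[[mc]] <- NA
  rows <- rows[, cols, drop = FALSE]
  for (i in seq_along(def$columns))
    rows[[i]] <- coerce_column(rows[[i]], def$columns[[i]]$type)

  reasons <- rep(NA_character_, nrow(rows))
  note <- function(sel, reason)
    reasons[sel & is.na(reasons)] <<- reason

  for (cc in def$columns)
    if (cc$required)
      note(is.na(rows[[cc$name]]), sprintf("required column %s is null",
                                           cc$name))
  # primary key uniqueness (within the batch and against loaded rows)
  pk_of <- function(df) do.call(paste, c(df[def$pk], sep = "\r"))
  pk <- pk_of(rows)
  note(duplicated(pk), sprintf("duplicate primary key (%s)",
                               paste(def$pk, collapse = ",")))
  existing <- pk_of(store$tables[[table]])
  note(pk %in% existing, sprintf("primary key already loaded (%s)",
                                 paste(def$pk, collapse = ",")))
  # foreign keys: non-null values must resolve against loaded content
  for (fk_col in names(def$fks)) {
    target <- def$fks[[fk_col]]
    vals <- rows[[fk_col]]
    ok <- is.na(vals) | vals %in% store$tables[[target[1]]][[target[2]]]
    note(!ok, sprintf("foreign key %s -> %s", fk_col, target[1]))
  }
  list(rows = rows[is.na(reasons), , drop = FALSE],
       rejects = data.frame(row = which(!is.na(reasons)),
                            reason = reasons[!is.na(reasons)]))
}

#' Load rows into the warehouse under constraint enforcement
#'
#' Tables are loaded in the canonical order (vocabulary tables, then
#' administrative, then visits, then event tables, then derived tables).
#' Rows violating required-column, primary-key or foreign-key constraints are
#' rejected and itemized; the report counts are exact
#' (attempted = loaded + rejected). Loading a clinical table before the
#' CONCEPT table has content is an ordering error.
#'
#' @param store a `cdm_store` from [create_cdm_store()].
#' @param tables named list of data.frames keyed by CDM table name.
#' @param enforce if FALSE, constraint violations are counted in the report
#'   but the rows are loaded anyway (the quality layer then judges them).
#' @return a `load_report` data.frame (table, attempted, loaded, rejected,
#'   seconds) with a `rejections` attribute (per-table data.frame of row
#'   numbers and reasons).
#' @export
load_cdm <- function(store, tables, enforce = TRUE) {
  unknown <- setdiff(names(tables), names(store$schema))
  if (length(unknown))
    etl_stop("input", "unknown CDM table(s): %s",
             paste(unknown, collapse = ", "))
  order_ <- intersect(names(store$schema), names(tables))
  report <- list(); rejections <- list()
  for (tab in order_) {
    if (tab %in% CLINICAL_TABLES && nrow(store$tables$CONCEPT) == 0)
      etl_stop("input",
               "vocabulary must be loaded before clinical table %s", tab)
    rows <- tables[[tab]]
    t0 <- proc.time()[["elapsed"]]
    res <- validate_rows(store, tab, rows)
    if (enforce) {
      store$tables[[tab]] <- rbind(store$tables[[tab]], res$rows)
      loaded <- nrow(res$rows); rejected <- nrow(res$rejects)
    } else {
      all_rows <- validate_rows(store, tab, rows)
      # load everything; violations stay visible to the quality checks
      coerced <- rows
      def <- store$schema[[tab]]
      cols <- vapply(def$columns, `[[`, character(1), "name")
      for (mc in setdiff(cols, names(coerced))) coerced[[mc]] <- NA
      coerced <- coerced[, cols, drop = FALSE]
      for (i in seq_along(def$columns))
        coerced[[i]] <- coerce_column(coerced[[i]], def$columns[[i]]$type)
      store$tables[[tab]] <- rbind(store$tables[[tab]], coerced)
      loaded <- nrow(coerced); rejected <- 0L
      res$rejects <- all_rows$rejects[0, ]
    }
    report[[tab]] <- data.frame(
      table = tab, attempted = nrow(rows), loaded = loaded,
      rejected = rejected,
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    rejections[[tab]] <- res$rejects
  }
  rep <- do.call(rbind, c(report, list(make.row.names = FALSE)))
  attr(rep, "rejections") <- rejections
  class(rep) <- c("load_report", "data.frame")
  rep
}

#' Persist / reload a file-backed store
#'
#' One CSV per table under the store's path (or an explicit directory).
#' @param store a `cdm_store`.
#' @param path directory; defaults to the store's own path.
#' @return the directory, invisibly.
#' @export
write_cdm_store <- function(store, path = store$path) {
  if (is.null(path)) etl_stop("input", "store has no path and none was given")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (tab in names(store$tables))
    utils::write.csv(store$tables[[tab]],
                     file.path(path, paste0(tab, ".csv")), row.names = FALSE)
  invisible(path)
}

# pull plain tables out of a store or pass a plain list through
cdm_tables <- function(cdm) {
  if (inherits(cdm, "cdm_store")) cdm$tables else cdm
}
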