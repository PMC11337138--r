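# One-call ETL driver: extract -> map -> transform -> load, with the
# intermediate artifacts returned for inspection. Each stage is also usable
# on its own (see the stage functions' documentation).

#' Run the full ETL pipeline over an XML export directory
#'
#' Extracts the per-patient XML documents into staging tables, builds and
#' annotates the mapping ledger against the vocabulary, runs the structural
#' transform (including derived OBSERVATION_PERIOD and DRUG_ERA), and loads
#' everything into a schema-validating warehouse.
#'
#' @param export_dir directory of patient XML documents.
#' @param store a `concept_store`; defaults to the bundled vocabulary
#'   fixture. The store is mutated: local concepts and "Maps to" links are
#'   registered during mapping.
#' @param ranges optional [plausibility_ranges()] applied as a transform-time
#'   outlier filter; `NULL` disables filtering (the quality layer still
#'   judges the loaded rows).
#' @param era an [era_config()].
#' @param enforce enforce constraints at load time (see [load_cdm()]).
#' @param store_path optional directory for a file-backed warehouse.
#' @return an `etl_result` list: `staging`, `ledger`, `store`, `cdm` (a
#'   `cdm_store`), `load_report`, `logs`, `person_map`.
#' @export
etl_pipeline <- function(export_dir, store = load_vocabulary_fixture(),
                         ranges = NULL, era = era_config(), enforce = TRUE,
                         store_path = NULL) {
  staging <- extract_all(export_dir)
  ledger <- build_ledger(staging, store)
  ledger <- annotate_ledger(ledger, store)
  built <- build_cdm(staging, ledger, store, ranges = ranges, era = era)
  cdm <- create_cdm_store(path = store_path)
  report <- load_cdm(cdm, built$tables, enforce = enforce)
  if (!is.null(store_path)) write_cdm_store(cdm)
  structure(list(staging = staging, ledger = ledger, store = store,
                 cdm = cdm, load_report = report, logs = built$logs,
                 person_map = built$person_map),
            class = "etl_result")
}

#' @export
print.etl_result <- function(x, ...) {
  cat("<etl_result>\n")
  print(x$load_report)
  invisible(x)
}

#' Persist a mapping ledger as CSV
#' @param ledger a `mapping_ledger`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.csv(ledger, path, row.names = FALSE)
  invisible(path)
}

#' Read a mapping ledger back from CSV
#' @param path CSV file written by [write_ledger()].
#' @return a `mapping_ledger` data.frame.
#' @export
read_ledger <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    item_id = "character", feature = "character", raw_label = "character",
    normalized_label = "character", source_vocabulary = "character",
    source_code = "character", unit = "character"))
  class(df) <- c("mapping_ledger", "data.frame")
  df
}
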