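# Source-vs-warehouse validation: five parameterized queries (two on the
# health center's activity, two on prescriptions, one on laboratory results)
# run against the warehouse and compared with ground truth, mirroring the
# manual checks a physician would run in the source software. Plus the
# three-tab dashboard data export (activity, prescriptions, laboratory).

REGISTRATION_CONCEPT_NAME <- "registration with family physician"

#' The five validation queries
#'
#' q1 (activity): registered patients per family physician, registrations
#' after the cutoff excluded. q2 (activity): consultations in a period.
#' q3/q4 (prescription): patients with at least one exposure to a given drug
#' ingredient in a period. q5 (laboratory): patients with a laboratory value
#' beyond a threshold in a period. Predicates are chosen to keep the
#' resulting patient counts small and hand-checkable.
#'
#' @param period two dates bounding q2-q5.
#' @param drug_a,drug_b ingredient names for the two prescription queries.
#' @param lab_analyte standard laboratory concept name for q5.
#' @param lab_threshold values strictly above this count for q5.
#' @return list of five `validation_query` descriptors.
#' @export
validation_queries <- function(period = c("2013-01-01", "2021-06-30"),
                               drug_a = "metformin",
                               drug_b = "amoxicillin",
                               lab_analyte = "Potassium",
                               lab_threshold = 5.0) {
  period <- as_iso_date(as.character(period))
  list(
    q1 = list(id = "q1", category = "activity",
              description = "registered patients per family physician"),
    q2 = list(id = "q2", category = "activity",
              description = "consultations in period", period = period),
    q3 = list(id = "q3", category = "prescription", ingredient = drug_a,
              description = sprintf("patients exposed to %s", drug_a),
              period = period),
    q4 = list(id = "q4", category = "prescription", ingredient = drug_b,
              description = sprintf("patients exposed to %s", drug_b),
              period = period),
    q5 = list(id = "q5", category = "laboratory", analyte = lab_analyte,
              threshold = lab_threshold,
              description = sprintf("patients with %s > %g", lab_analyte,
                                    lab_threshold),
              period = period)
  )
}

concept_id_by_name <- function(tabs, name, vocabulary = NULL) {
  con <- tabs$CONCEPT
  sel <- con$concept_name == name
  if (!is.null(vocabulary)) sel <- sel & con$vocabulary_id %in% vocabulary
  ids <- con$concept_id[sel]
  if (!length(ids)) etl_stop("lookup", "concept named '%s' not found", name)
  ids[1]
}

# drug concepts reaching the named ingredient (the ingredient itself plus
# every drug-level concept linked via "RxNorm has ingredient")
ingredient_concept_set <- function(tabs, ingredient) {
  ing_id <- concept_id_by_name(tabs, ingredient,
                               c("RxNorm", "RxNorm Ingredient"))
  rel <- tabs$CONCEPT_RELATIONSHIP
  drugs <- rel$concept_id_1[rel$relationship_id == "RxNorm has ingredient" &
                              rel$concept_id_2 == ing_id]
  c(ing_id, drugs)
}

#' Run the validation queries against the warehouse
#'
#' All counts are restricted to events on or before the cutoff date (the
#' extraction date); q1 additionally excludes patients whose registration
#' with their family physician is dated after the cutoff.
#'
#' @param cdm a `cdm_store` or named list of CDM tables.
#' @param queries from [validation_queries()].
#' @param cutoff_date the extraction date.
#' @return named list of query results (q1 is a named vector of per-physician
#'   patient counts; q2-q5 are scalar counts).
#' @export
run_validation_queries <- function(cdm, queries = validation_queries(),
                                   cutoff_date = as.Date("2021-06-30")) {
  tabs <- cdm_tables(cdm)
  cutoff <- as_iso_date(as.character(cutoff_date))
  in_window <- function(d, period)
    !is.na(d) & d >= period[1] & d <= pmin(period[2], cutoff)

  reg_id <- concept_id_by_name(tabs, REGISTRATION_CONCEPT_NAME)
  obs <- tabs$OBSERVATION
  reg <- obs[obs$observation_concept_id == reg_id, , drop = FALSE]
  registered <- reg$person_id[!is.na(reg$observation_date) &
                                reg$observation_date <= cutoff]
  p <- tabs$PERSON[tabs$PERSON$person_id %in% registered, , drop = FALSE]
  prov <- tabs$PROVIDER
  phys <- prov$provider_source_value[match(p$provider_id, prov$provider_id)]
  q1 <- table(phys)
  q1 <- stats::setNames(as.integer(q1), names(q1))

  v <- tabs$VISIT_OCCURRENCE
  q2 <- sum(in_window(v$visit_start_date, queries$q2$period))

  drug_query <- function(q) {
    set <- ingredient_concept_set(tabs, q$ingredient)
    dx <- tabs$DRUG_EXPOSURE
    sel <- dx$drug_concept_id %in% set &
      in_window(dx$drug_exposure_start_date, q$period)
    length(unique(dx$person_id[sel]))
  }
  q3 <- drug_query(queries$q3)
  q4 <- drug_query(queries$q4)

  lab_id <- concept_id_by_name(tabs, queries$q5$analyte, "LOINC")
  mm <- tabs$MEASUREMENT
  sel <- !is.na(mm$measurement_concept_id) &
    mm$measurement_concept_id == lab_id &
    !is.na(mm$value_as_number) & mm$value_as_number > queries$q5$threshold &
    in_window(mm$measurement_date, queries$q5$period)
  q5 <- length(unique(mm$person_id[sel]))

  list(q1 = q1, q2 = q2, q3 = q3, q4 = q4, q5 = q5)
}

# ground truth for the same five queries, from the generator manifest
manifest_query_truth <- function(manifest, queries = validation_queries(),
                                 cutoff_date = as.Date("2021-06-30")) {
  cutoff <- as_iso_date(as.character(cutoff_date))
  tr <- manifest$truth
  in_window <- function(d, period) {
    d <- as_iso_date(d)
    !is.na(d) & d >= period[1] & d <= pmin(period[2], cutoff)
  }
  pats <- tr$patients
  reg_ok <- as_iso_date(pats$registration_date) <= cutoff
  q1 <- table(pats$physician[reg_ok])
  q1 <- stats::setNames(as.integer(q1), names(q1))
  q2 <- sum(in_window(tr$consultations$date, queries$q2$period))
  drug_truth <- function(q) {
    sel <- grepl(q$ingredient, tr$prescriptions$name, fixed = TRUE) &
      in_window(tr$prescriptions$date, q$period)
    length(unique(tr$prescriptions$patient_id[sel]))
  }
  q3 <- drug_truth(queries$q3)
  q4 <- drug_truth(queries$q4)
  sel <- tr$lab_results$analyte == tolower(queries$q5$analyte) &
    tr$lab_results$value > queries$q5$threshold &
    in_window(tr$lab_results$date, queries$q5$period)
  q5 <- length(unique(tr$lab_results$patient_id[sel]))
  list(q1 = q1, q2 = q2, q3 = q3, q4 = q4, q5 = q5)
}

#' Compare warehouse query results with source ground truth
#'
#' Per query: warehouse value, source-truth value, match flag, and a
#' mandatory explanation slot for mismatches (mirroring the manual
#' reconciliation of source-vs-warehouse differences).
#'
#' @param results from [run_validation_queries()].
#' @param manifest the generator `ground_truth_manifest` standing in for the
#'   source software's answers.
#' @param queries the query descriptors used.
#' @param cutoff_date the extraction date applied to both sides.
#' @param explanations optional named character vector (query id ->
#'   explanation) documenting understood mismatches.
#' @return a `concordance_report` data.frame.
#' @export
compare_to_source <- function(results, manifest,
                              queries = validation_queries(),
                              cutoff_date = as.Date("2021-06-30"),
                              explanations = NULL) {
  truth <- manifest_query_truth(manifest, queries, cutoff_date)
  fmt <- function(x) {
    if (length(x) > 1 || !is.null(names(x)))
      paste(sprintf("%s=%s", names(x), x), collapse = ";")
    else as.character(x)
  }
  rows <- lapply(names(truth), function(q) {
    w <- results[[q]]; s <- truth[[q]]
    match_ <- isTRUE(all.equal(sort(fmt(w)), sort(fmt(s)))) ||
      identical(fmt(w), fmt(s))
    expl <- if (match_) NA_character_
      else (explanations[[q]] %||% "unexplained discrepancy")
    data.frame(query = q, category = queries[[q]]$category,
               description = queries[[q]]$description,
               warehouse = fmt(w), source = fmt(s), match = match_,
               explanation = expl)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("concordance_report", "data.frame")
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Source-vs-warehouse concordance: %d/%d queries match\n",
              sum(x$match), nrow(x)))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %s [%s] warehouse=%s source=%s %s\n", x$query[i],
                x$category[i], x$warehouse[i], x$source[i],
                if (x$match[i]) "OK" else paste0("MISMATCH (",
                                                 x$explanation[i], ")")))
  invisible(x)
}

#' Export the three dashboard datasets
#'
#' Activity: patients and consultations per family physician per year.
#' Prescriptions: exposure counts per ATC drug class per year.
#' Laboratory: a distribution summary per measured laboratory concept.
#'
#' @param cdm a `cdm_store` or named list of CDM tables.
#' @param ranges optional [plausibility_ranges()] for out-of-range counts.
#' @return list of three data.frames: `activity`, `prescriptions`,
#'   `laboratory` (empty with headers when the CDM is empty).
#' @export
export_dashboard_data <- function(cdm, ranges = NULL) {
  tabs <- cdm_tables(cdm)
  v <- tabs$VISIT_OCCURRENCE; prov <- tabs$PROVIDER

  activity <- data.frame(physician = character(0), year = integer(0),
                         n_patients = integer(0), n_consultations = integer(0))
  if (!is.null(v) && nrow(v)) {
    phys <- prov$provider_source_value[match(v$provider_id,
                                             prov$provider_id)]
    year <- as.integer(format(v$visit_start_date, "%Y"))
    key <- paste(phys, year)
    sp <- split(seq_len(nrow(v)), key)
    activity <- do.call(rbind, lapply(sp, function(ii) data.frame(
      physician = phys[ii[1]], year = year[ii[1]],
      n_patients = length(unique(v$person_id[ii])),
      n_consultations = length(ii))))
    activity <- activity[order(activity$physician, activity$year), ]
    rownames(activity) <- NULL
  }

  prescriptions <- data.frame(atc_class = character(0), year = integer(0),
                              n_exposures = integer(0))
  dx <- tabs$DRUG_EXPOSURE
  if (!is.null(dx) && nrow(dx)) {
    rel <- tabs$CONCEPT_RELATIONSHIP
    a2r <- rel[rel$relationship_id == "ATC to RxNorm", , drop = FALSE]
    con <- tabs$CONCEPT
    atc_of <- stats::setNames(
      con$concept_code[match(a2r$concept_id_1, con$concept_id)],
      a2r$concept_id_2)
    cls <- atc_of[as.character(dx$drug_concept_id)]
    cls[is.na(cls)] <- "unmapped"
    year <- as.integer(format(dx$drug_exposure_start_date, "%Y"))
    agg <- table(atc_class = cls, year = year)
    prescriptions <- as.data.frame(agg, stringsAsFactors = FALSE)
    names(prescriptions) <- c("atc_class", "year", "n_exposures")
    prescriptions <- prescriptions[prescriptions$n_exposures > 0, ]
    prescriptions$year <- as.integer(prescriptions$year)
    prescriptions <- prescriptions[order(prescriptions$atc_class,
                                         prescriptions$year), ]
    rownames(prescriptions) <- NULL
  }

  laboratory <- data.frame(concept_id = numeric(0), concept_name = character(0),
                           n = integer(0), min = numeric(0), p25 = numeric(0),
                           median = numeric(0), p75 = numeric(0),
                           max = numeric(0), out_of_range = integer(0))
  mm <- tabs$MEASUREMENT
  if (!is.null(mm) && nrow(mm)) {
    lab <- mm[mm$measurement_source_type_id %in% "laboratory" &
                mm$measurement_concept_id != 0, , drop = FALSE]
    for (cid in sort(unique(lab$measurement_concept_id))) {
      d <- value_distribution(tabs, cid, ranges)
      laboratory <- rbind(laboratory, data.frame(
        concept_id = d$concept_id, concept_name = d$concept_name, n = d$n,
        min = d$min, p25 = d$p25, median = d$median, p75 = d$p75,
        max = d$max, out_of_range = d$out_of_range))
    }
  }
  list(activity = activity, prescriptions = prescriptions,
       laboratory = laboratory)
}

#' Write the dashboard datasets to disk (CSV + JSON)
#'
#' @param data from [export_dashboard_data()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_dashboard_data <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(data)) {
    utils::write.csv(data[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(data[[nm]], file.path(dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(dir)
}
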