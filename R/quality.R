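# Kahn-framework data-quality assessment over the loaded CDM, in the
# Verification context: Conformance (keys, referential integrity, required
# fields, concept-domain agreement), Completeness (unmapped concepts,
# missing values), Plausibility (value ranges, chronology against birth,
# death and the extraction date). The registry is data-driven so sites can
# extend it.

quality_check <- function(id, category, description, fn, threshold = 0) {
  stopifnot(category %in% c("Conformance", "Completeness", "Plausibility"),
            threshold >= 0, threshold <= 1)
  list(id = id, category = category, description = description,
       context = "Verification", threshold = threshold, fn = fn)
}

fk_check <- function(id, table, column, target_table, target_column,
                     description) {
  quality_check(id, "Conformance", description, function(tabs, ranges) {
    df <- tabs[[table]]
    if (is.null(df) || !nrow(df)) return(list(violations = 0L, total = 0L))
    vals <- df[[column]]
    ok <- is.na(vals) | vals %in% tabs[[target_table]][[target_column]]
    list(violations = sum(!ok), total = nrow(df),
         sample = utils::head(df[[1]][!ok], 5))
  })
}

pk_check <- function(id, table, column) {
  quality_check(id, "Conformance",
                sprintf("%s.%s is unique and non-null", table, column),
    function(tabs, ranges) {
      df <- tabs[[table]]
      if (is.null(df) || !nrow(df)) return(list(violations = 0L, total = 0L))
      bad <- is.na(df[[column]]) | duplicated(df[[column]])
      list(violations = sum(bad), total = nrow(df),
           sample = utils::head(df[[column]][bad], 5))
    })
}

domain_check <- function(id, table, column, domains, description) {
  quality_check(id, "Conformance", description, function(tabs, ranges) {
    df <- tabs[[table]]
    if (is.null(df) || !nrow(df)) return(list(violations = 0L, total = 0L))
    con <- tabs$CONCEPT
    dom <- con$domain_id[match(df[[column]], con$concept_id)]
    bad <- !is.na(df[[column]]) & df[[column]] != 0 &
      (is.na(dom) | !dom %in% domains)
    list(violations = sum(bad), total = nrow(df),
         sample = utils::head(df[[column]][bad], 5))
  })
}

event_tables <- function() list(
  VISIT_OCCURRENCE = "visit_start_date", MEASUREMENT = "measurement_date",
  DRUG_EXPOSURE = "drug_exposure_start_date", NOTE = "note_date",
  OBSERVATION = "observation_date")

#' The default data-quality check registry
#'
#' Declarative list of checks grouped into the three Kahn categories; each
#' check counts violating rows over a total and fails when the violation
#' fraction exceeds its severity threshold (default 0: any violation fails).
#'
#' @return list of check definitions.
#' @export
default_quality_registry <- function() {
  checks <- list(
    pk_check("conf_person_pk", "PERSON", "person_id"),
    pk_check("conf_visit_pk", "VISIT_OCCURRENCE", "visit_occurrence_id"),
    pk_check("conf_measurement_pk", "MEASUREMENT", "measurement_id"),
    fk_check("conf_visit_person_fk", "VISIT_OCCURRENCE", "person_id",
             "PERSON", "person_id", "visits reference an existing person"),
    fk_check("conf_measurement_person_fk", "MEASUREMENT", "person_id",
             "PERSON", "person_id",
             "measurements reference an existing person"),
    fk_check("conf_measurement_visit_fk", "MEASUREMENT",
             "visit_occurrence_id", "VISIT_OCCURRENCE",
             "visit_occurrence_id",
             "visit-linked measurements reference an existing visit"),
    fk_check("conf_drug_person_fk", "DRUG_EXPOSURE", "person_id",
             "PERSON", "person_id",
             "drug exposures reference an existing person"),
    fk_check("conf_drug_visit_fk", "DRUG_EXPOSURE", "visit_occurrence_id",
             "VISIT_OCCURRENCE", "visit_occurrence_id",
             "visit-linked drug exposures reference an existing visit"),
    fk_check("conf_note_person_fk", "NOTE", "person_id", "PERSON",
             "person_id", "notes reference an existing person"),
    fk_check("conf_observation_person_fk", "OBSERVATION", "person_id",
             "PERSON", "person_id",
             "observations reference an existing person"),
    fk_check("conf_death_person_fk", "DEATH", "person_id", "PERSON",
             "person_id", "deaths reference an existing person"),
    fk_check("conf_era_person_fk", "DRUG_ERA", "person_id", "PERSON",
             "person_id", "drug eras reference an existing person"),
    domain_check("conf_measurement_domain", "MEASUREMENT",
                 "measurement_concept_id", "Measurement",
                 "measurement concepts belong to the Measurement domain"),
    domain_check("conf_drug_domain", "DRUG_EXPOSURE", "drug_concept_id",
                 "Drug", "drug concepts belong to the Drug domain"),
    quality_check("conf_visit_concept", "Conformance",
                  "visits carry the primary-care visit concept",
      function(tabs, ranges) {
        df <- tabs$VISIT_OCCURRENCE
        if (is.null(df) || !nrow(df))
          return(list(violations = 0L, total = 0L))
        bad <- df$visit_concept_id != PRIMARY_CARE_VISIT
        list(violations = sum(bad), total = nrow(df),
             sample = utils::head(df$visit_occurrence_id[bad], 5))
      }),

    quality_check("comp_person_gender", "Completeness",
                  "every person has a mapped gender concept",
      function(tabs, ranges) {
        df <- tabs$PERSON
        if (is.null(df) || !nrow(df))
          return(list(violations = 0L, total = 0L))
        bad <- is.na(df$gender_concept_id) | df$gender_concept_id == 0
        list(violations = sum(bad), total = nrow(df),
             sample = utils::head(df$person_id[bad], 5))
      }),
    quality_check("comp_person_birth_year", "Completeness",
                  "every person has a year of birth",
      function(tabs, ranges) {
        df <- tabs$PERSON
        if (is.null(df) || !nrow(df))
          return(list(violations = 0L, total = 0L))
        bad <- is.na(df$year_of_birth)
        list(violations = sum(bad), total = nrow(df),
             sample = utils::head(df$person_id[bad], 5))
      }),
    quality_check("comp_measurement_mapped", "Completeness",
                  "measurement concepts are mapped (not concept 0)",
      function(tabs, ranges) {
        df <- tabs$MEASUREMENT
        if (is.null(df) || !nrow(df))
          return(list(violations = 0L, total = 0L))
        bad <- df$measurement_concept_id == 0
        list(violations = sum(bad), total = nrow(df),
             sample = utils::head(df$measurement_id[bad], 5))
      }),
    quality_check("comp_drug_mapped", "Completeness",
                  "drug exposures are mapped (not concept 0)",
      function(tabs, ranges) {
        df <- tabs$DRUG_EXPOSURE
        if (is.null(df) || !nrow(df))
          return(list(violations = 0L, total = 0L))
        bad <- df$drug_concept_id == 0
        list(violations = sum(bad), total = nrow(df),
             sample = utils::head(df$drug_exposure_id[bad], 5))
      }),
    quality_check("comp_event_dates", "Completeness",
                  "clinical events carry a date",
      function(tabs, ranges) {
        viol <- 0L; total <- 0L; samp <- c()
        for (tab in names(event_tables())) {
          df <- tabs[[tab]]
          if (is.null(df) || !nrow(df)) next
          d <- df[[event_tables()[[tab]]]]
          viol <- viol + sum(is.na(d)); total <- total + nrow(df)
          samp <- c(samp, utils::head(df[[1]][is.na(d)], 2))
        }
        list(violations = viol, total = total, sample = samp)
      }),

    quality_check("plaus_birth_year", "Plausibility",
                  "years of birth lie within the plausible bounds",
      function(tabs, ranges) {
        df <- tabs$PERSON
        if (is.null(df) || !nrow(df))
          return(list(violations = 0L, total = 0L))
        b <- ranges$birth_year_bounds
        bad <- !is.na(df$year_of_birth) &
          (df$year_of_birth < b[1] | df$year_of_birth > b[2])
        list(violations = sum(bad), total = nrow(df),
             sample = utils::head(df$person_id[bad], 5))
      }),
    quality_check("plaus_event_after_death", "Plausibility",
                  "no event is dated after death (plus the grace period)",
      function(tabs, ranges) {
        death <- tabs$DEATH
        if (is.null(death) || !nrow(death))
          return(list(violations = 0L, total = 0L))
        grace <- ranges$post_death_grace_days
        limit <- stats::setNames(death$death_date + grace, death$person_id)
        viol <- 0L; total <- 0L; samp <- c()
        for (tab in names(event_tables())) {
          df <- tabs[[tab]]
          if (is.null(df) || !nrow(df)) next
          d <- df[[event_tables()[[tab]]]]
          lim <- limit[as.character(df$person_id)]
          bad <- !is.na(lim) & !is.na(d) & d > lim
          viol <- viol + sum(bad); total <- total + nrow(df)
          samp <- c(samp, utils::head(paste(tab, df[[1]][bad]), 2))
        }
        list(violations = viol, total = total, sample = samp)
      }),
    quality_check("plaus_event_before_birth", "Plausibility",
                  "no event predates the person's birth year",
      function(tabs, ranges) {
        p <- tabs$PERSON
        if (is.null(p) || !nrow(p))
          return(list(violations = 0L, total = 0L))
        birth <- stats::setNames(p$year_of_birth, p$person_id)
        viol <- 0L; total <- 0L; samp <- c()
        for (tab in names(event_tables())) {
          df <- tabs[[tab]]
          if (is.null(df) || !nrow(df)) next
          d <- df[[event_tables()[[tab]]]]
          by <- birth[as.character(df$person_id)]
          bad <- !is.na(by) & !is.na(d) &
            as.integer(format(d, "%Y")) < by
          viol <- viol + sum(bad); total <- total + nrow(df)
          samp <- c(samp, utils::head(paste(tab, df[[1]][bad]), 2))
        }
        list(violations = viol, total = total, sample = samp)
      }),
    quality_check("plaus_event_before_extraction", "Plausibility",
                  "no event is dated after the extraction date",
      function(tabs, ranges) {
        cutoff <- ranges$extraction_date
        viol <- 0L; total <- 0L; samp <- c()
        for (tab in names(event_tables())) {
          df <- tabs[[tab]]
          if (is.null(df) || !nrow(df)) next
          d <- df[[event_tables()[[tab]]]]
          bad <- !is.na(d) & d > cutoff
          viol <- viol + sum(bad); total <- total + nrow(df)
          samp <- c(samp, utils::head(paste(tab, df[[1]][bad]), 2))
        }
        list(violations = viol, total = total, sample = samp)
      }),
    quality_check("plaus_measurement_range", "Plausibility",
                  "measurement values lie within their plausibility range",
      function(tabs, ranges) {
        df <- tabs$MEASUREMENT
        mr <- ranges$measurement_ranges
        if (is.null(df) || !nrow(df) || is.null(mr))
          return(list(violations = 0L, total = 0L))
        m <- match(df$measurement_concept_id, mr$concept_id)
        bad <- !is.na(m) & !is.na(df$value_as_number) &
          (df$value_as_number < mr$low[m] | df$value_as_number > mr$high[m])
        list(violations = sum(bad), total = nrow(df),
             sample = utils::head(df$measurement_id[bad], 5))
      }),
    quality_check("plaus_exposure_chronology", "Plausibility",
                  "drug exposure ends do not precede their starts",
      function(tabs, ranges) {
        df <- tabs$DRUG_EXPOSURE
        if (is.null(df) || !nrow(df))
          return(list(violations = 0L, total = 0L))
        bad <- !is.na(df$drug_exposure_end_date) &
          df$drug_exposure_end_date < df$drug_exposure_start_date
        list(violations = sum(bad), total = nrow(df),
             sample = utils::head(df$drug_exposure_id[bad], 5))
      })
  )
  stats::setNames(checks, vapply(checks, `[[`, character(1), "id"))
}

#' Run the quality-check registry against a CDM
#'
#' Executes every registered check. On an empty CDM all checks pass
#' vacuously with total 0 (reported, not an error).
#'
#' @param cdm a `cdm_store` or plain named list of CDM tables.
#' @param registry list of checks from [default_quality_registry()].
#' @param ranges a [plausibility_ranges()] object.
#' @return a `quality_results` data.frame: check id, category, description,
#'   status ("pass"/"fail"), violations, total, with an `offending`
#'   attribute holding a small sample of offending keys per failed check.
#' @export
run_checks <- function(cdm, registry = default_quality_registry(),
                       ranges = plausibility_ranges()) {
  tabs <- cdm_tables(cdm)
  rows <- list(); samples <- list()
  for (chk in registry) {
    res <- chk$fn(tabs, ranges)
    frac <- if (res$total > 0) res$violations / res$total else 0
    status <- if (frac > chk$threshold) "fail" else "pass"
    rows[[chk$id]] <- data.frame(
      check_id = chk$id, category = chk$category,
      description = chk$description, status = status,
      violations = res$violations, total = res$total)
    if (status == "fail") samples[[chk$id]] <- res$sample %||% character(0)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "offending") <- samples
  class(out) <- c("quality_results", "data.frame")
  out
}

#' Summarize quality results by Kahn category
#'
#' @param results a `quality_results` data.frame from [run_checks()].
#' @return data.frame with one row per category: checks, passed, failed.
#'   The category totals sum to the registry size.
#' @export
summarize_checks <- function(results) {
  if (!nrow(results)) etl_stop("input", "no quality results to summarize")
  cats <- c("Conformance", "Completeness", "Plausibility")
  out <- do.call(rbind, lapply(cats, function(cat) {
    sub <- results[results$category == cat, , drop = FALSE]
    data.frame(category = cat, checks = nrow(sub),
               passed = sum(sub$status == "pass"),
               failed = sum(sub$status == "fail"))
  }))
  out
}

#' @export
print.quality_results <- function(x, ...) {
  s <- summarize_checks(x)
  cat("Data quality assessment (Kahn framework, Verification context)\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-13s %2d checks, %2d passed, %2d failed\n",
                s$category[i], s$checks[i], s$passed[i], s$failed[i]))
  fails <- x[x$status == "fail", , drop = FALSE]
  if (nrow(fails)) {
    cat("Failing checks:\n")
    for (i in seq_len(nrow(fails)))
      cat(sprintf("  %-28s %d/%d rows: %s\n", fails$check_id[i],
                  fails$violations[i], fails$total[i],
                  fails$description[i]))
  }
  invisible(x)
}

#' Distribution summary of a measured concept
#'
#' Exact order statistics (min, quartiles, median, max) over the stored
#' values of one measurement concept, plus the out-of-range count under the
#' supplied plausibility ranges.
#'
#' @param cdm a `cdm_store` or named list of CDM tables.
#' @param concept_id a measurement concept present in MEASUREMENT.
#' @param ranges optional [plausibility_ranges()].
#' @return a `distribution_summary` list: concept_id, concept_name, n, min,
#'   p25, median, p75, max, out_of_range.
#' @export
value_distribution <- function(cdm, concept_id, ranges = NULL) {
  tabs <- cdm_tables(cdm)
  df <- tabs$MEASUREMENT
  sel <- !is.na(df$measurement_concept_id) &
    df$measurement_concept_id == concept_id
  vals <- df$value_as_number[sel]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    etl_stop("lookup", "no measurement rows for concept %s", concept_id)
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
  oor <- 0L
  if (!is.null(ranges) && !is.null(ranges$measurement_ranges)) {
    mr <- ranges$measurement_ranges
    m <- match(concept_id, mr$concept_id)
    if (!is.na(m)) oor <- sum(vals < mr$low[m] | vals > mr$high[m])
  }
  nm <- tabs$CONCEPT$concept_name[match(concept_id, tabs$CONCEPT$concept_id)]
  structure(list(concept_id = concept_id,
                 concept_name = nm %||% NA_character_, n = length(vals),
                 min = min(vals), p25 = q[1], median = q[2], p75 = q[3],
                 max = max(vals), out_of_range = oor),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf(
    "%s (concept %s): n=%d  min=%.2f  p25=%.2f  median=%.2f  p75=%.2f  max=%.2f  out-of-range=%d\n",
    x$concept_name, format(x$concept_id, scientific = FALSE), x$n, x$min,
    x$p25, x$median, x$p75, x$max, x$out_of_range))
  invisible(x)
}
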