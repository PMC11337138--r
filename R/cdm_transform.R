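# Structural mapping: staging entities + mapping ledger -> OMOP CDM v5.4
# subset rows. Artificial identifiers come from per-table monotonic
# sequences; source identifiers survive only in *_source_value columns.
# Derived tables: OBSERVATION_PERIOD ([min, max] of each person's dated
# events) and DRUG_ERA (ingredient-level persistence-window merge).

EHR_TYPE <- 32817            # provenance type concept: EHR
LAB_TYPE <- 32856            # measurement type: Lab
PHYSICAL_EXAM_TYPE <- 44818701  # measurement type: from physical examination
PRIMARY_CARE_VISIT <- 38004247  # Ambulatory Primary Care Clinic/Center

#' Drug-era derivation settings
#'
#' @param persistence_window days two successive exposures to the same
#'   ingredient may be apart and still belong to one era (default 30, the
#'   OHDSI convention).
#' @param exposure_end_rule how an exposure's end date is derived when built
#'   from prescriptions: `start_plus_days_supply` (end = start +
#'   days_supply - 1 when days_supply is present, else start) or
#'   `start_only` (end = start).
#' @return an `era_config` list.
#' @export
era_config <- function(persistence_window = 30,
                       exposure_end_rule = c("start_plus_days_supply",
                                             "start_only")) {
  if (persistence_window < 0)
    etl_stop("config", "persistence_window must be >= 0")
  list(persistence_window = persistence_window,
       exposure_end_rule = match.arg(exposure_end_rule))
}

#' Plausibility ranges for measurement values and demographics
#'
#' @param measurement_ranges data.frame with columns `concept_id`, `low`,
#'   `high` (in the concept's reported unit); `low < high`.
#' @param birth_year_bounds inclusive `[min, max]` plausible years of birth.
#' @param post_death_grace_days events this many days after death are still
#'   tolerated (default 0).
#' @param extraction_date no event may be dated after this.
#' @return a `plausibility_ranges` list.
#' @export
plausibility_ranges <- function(measurement_ranges = NULL,
                                birth_year_bounds = c(1900, 2021),
                                post_death_grace_days = 0,
                                extraction_date = as.Date("2021-06-30")) {
  if (!is.null(measurement_ranges)) {
    stopifnot(all(c("concept_id", "low", "high") %in%
                    names(measurement_ranges)))
    if (any(measurement_ranges$low >= measurement_ranges$high))
      etl_stop("config", "plausibility range with low >= high")
  }
  structure(list(measurement_ranges = measurement_ranges,
                 birth_year_bounds = birth_year_bounds,
                 post_death_grace_days = post_death_grace_days,
                 extraction_date = as_iso_date(as.character(extraction_date))),
            class = "plausibility_ranges")
}

#' Default plausibility ranges resolved against a concept store
#'
#' Clinical ranges per standard measurement concept, in the unit the
#' synthetic laboratories report (e.g. blood potassium 1.5-8 mmol/L).
#'
#' @param store a `concept_store` (concept ids are resolved by name).
#' @param ... passed to [plausibility_ranges()].
#' @return a `plausibility_ranges` object.
#' @export
default_plausibility_ranges <- function(store, ...) {
  byname <- function(nm) {
    id <- store$concept$concept_id[store$concept$concept_name == nm &
                                     store$concept$standard_concept == "S"]
    if (length(id)) id[1] else NA_real_
  }
  spec <- list(
    Potassium = c(1.5, 8), Sodium = c(110, 180), Creatinine = c(1, 2000),
    `C-reactive protein` = c(0, 600), Hemoglobin = c(2, 25),
    Glucose = c(0.5, 50),
    `Body weight` = c(1, 400), `Body height` = c(30, 250),
    `Heart rate` = c(20, 250), `Systolic blood pressure` = c(50, 260),
    `Diastolic blood pressure` = c(30, 160), `Body mass index` = c(8, 100))
  ids <- vapply(names(spec), byname, numeric(1))
  keep <- !is.na(ids)
  mr <- data.frame(concept_id = ids[keep],
                   low = vapply(spec[keep], `[`, numeric(1), 1),
                   high = vapply(spec[keep], `[`, numeric(1), 2))
  plausibility_ranges(measurement_ranges = mr, ...)
}

# -- demographics -----------------------------------------------------------

#' Build PERSON, LOCATION, PROVIDER, CARE_SITE and DEATH rows
#'
#' One PersonRow per source patient with a fresh sequential person_id; the
#' source patient identifier is kept only in person_source_value. Addresses
#' are deduplicated into LOCATION rows; there is exactly one CARE_SITE. An
#' unmapped sex value yields gender_concept_id 0 plus a completeness warning
#' (not a failure).
#'
#' @param staging a `staging_store`.
#' @param ledger an annotated `mapping_ledger` (for the sex mapping).
#' @param seqs named list of [id_sequence()]s (created on demand).
#' @return list of data.frames: PERSON, LOCATION, PROVIDER, CARE_SITE,
#'   DEATH, plus `person_map` (patient_id -> person_id),
#'   `provider_map`, and a `warnings` character vector.
#' @export
build_demographics <- function(staging, ledger, seqs = list()) {
  pats <- staging$patients
  if (!nrow(pats)) etl_stop("input", "staging has no patients")
  warnings <- character(0)

  addr <- staging$addresses
  addr_key <- paste(addr$line, addr$town, addr$postal_code, addr$country,
                    sep = "\r")
  uniq <- !duplicated(addr_key)
  loc_seq <- seqs$LOCATION %||% id_sequence("LOCATION")
  locations <- data.frame(
    location_id = next_ids(loc_seq, sum(uniq)),
    address_1 = addr$line[uniq], city = addr$town[uniq],
    zip = addr$postal_code[uniq], country_source_value = addr$country[uniq])
  loc_of_key <- stats::setNames(locations$location_id, addr_key[uniq])
  patient_loc <- stats::setNames(
    loc_of_key[addr_key][!duplicated(addr$patient_id)],
    addr$patient_id[!duplicated(addr$patient_id)])

  care_site <- data.frame(
    care_site_id = 1L, care_site_name = "Multidisciplinary health center",
    place_of_service_concept_id = PRIMARY_CARE_VISIT,
    location_id = NA_integer_, care_site_source_value = "MHC")

  prov_seq <- seqs$PROVIDER %||% id_sequence("PROVIDER")
  prov_src <- sort(unique(pats$physician_id))
  providers <- data.frame(
    provider_id = next_ids(prov_seq, length(prov_src)),
    specialty_concept_id = 38004446, care_site_id = 1L,
    provider_source_value = prov_src)
  provider_map <- stats::setNames(providers$provider_id, prov_src)

  person_seq <- seqs$PERSON %||% id_sequence("PERSON")
  person_ids <- next_ids(person_seq, nrow(pats))
  gender <- vapply(pats$sex, function(s) {
    if (is.na(s)) return(0)
    ledger_lookup(ledger, "sex", s)$concept
  }, numeric(1), USE.NAMES = FALSE)
  n_unmapped <- sum(gender == 0)
  if (n_unmapped)
    warnings <- c(warnings, sprintf(
      "%d patient(s) with missing or unmapped sex: gender_concept_id set to 0",
      n_unmapped))
  persons <- data.frame(
    person_id = person_ids, gender_concept_id = gender,
    year_of_birth = suppressWarnings(as.integer(pats$year_of_birth)),
    race_concept_id = 0, ethnicity_concept_id = 0,
    location_id = unname(patient_loc[pats$patient_id]),
    provider_id = unname(provider_map[pats$physician_id]),
    care_site_id = 1L, person_source_value = pats$patient_id,
    gender_source_value = pats$sex)
  person_map <- stats::setNames(person_ids, pats$patient_id)

  deaths <- staging$deaths
  death_rows <- data.frame(
    person_id = unname(person_map[deaths$patient_id]),
    death_date = as_iso_date(deaths$date),
    death_type_concept_id = rep(EHR_TYPE, nrow(deaths)))

  list(PERSON = persons, LOCATION = locations, PROVIDER = providers,
       CARE_SITE = care_site, DEATH = death_rows,
       person_map = person_map, provider_map = provider_map,
       warnings = warnings)
}

# -- visits -----------------------------------------------------------------

#' Build VISIT_OCCURRENCE rows from consultations
#'
#' One row per consultation, visit_concept_id 38004247 (Ambulatory Primary
#' Care Clinic/Center), start date = end date = consultation date (primary
#' care visits are single-day). Duplicate source consultation identifiers
#' collapse to one row.
#'
#' @param consultations staging consultations.
#' @param person_map named vector source patient id -> person_id.
#' @param provider_of_person optional named vector person_id -> provider_id.
#' @param seq an [id_sequence()] for visit_occurrence_id.
#' @return list(VISIT_OCCURRENCE, visit_map) where `visit_map` maps source
#'   consultation ids to visit_occurrence_ids.
#' @export
build_visits <- function(consultations, person_map,
                         provider_of_person = NULL,
                         seq = id_sequence("VISIT_OCCURRENCE")) {
  cons <- consultations[!duplicated(consultations$consultation_id), ,
                        drop = FALSE]
  if (!nrow(cons)) {
    empty <- data.frame(
      visit_occurrence_id = integer(0), person_id = integer(0),
      visit_concept_id = numeric(0),
      visit_start_date = as.Date(character(0)),
      visit_end_date = as.Date(character(0)),
      visit_type_concept_id = numeric(0), provider_id = integer(0),
      care_site_id = integer(0), visit_source_value = character(0))
    return(list(VISIT_OCCURRENCE = empty, visit_map = integer(0)))
  }
  unknown <- setdiff(cons$patient_id, names(person_map))
  if (length(unknown))
    etl_stop("integrity", "consultations reference unknown patient(s): %s",
             paste(unknown, collapse = ", "))
  ids <- next_ids(seq, nrow(cons))
  person_id <- unname(person_map[cons$patient_id])
  rows <- data.frame(
    visit_occurrence_id = ids, person_id = person_id,
    visit_concept_id = PRIMARY_CARE_VISIT,
    visit_start_date = as_iso_date(cons$date),
    visit_end_date = as_iso_date(cons$date),
    visit_type_concept_id = EHR_TYPE,
    provider_id = if (is.null(provider_of_person)) NA_integer_
      else unname(provider_of_person[as.character(person_id)]),
    care_site_id = 1L, visit_source_value = cons$consultation_id)
  list(VISIT_OCCURRENCE = rows,
       visit_map = stats::setNames(ids, cons$consultation_id))
}

# -- measurements -----------------------------------------------------------

#' Build MEASUREMENT rows from biometrics and laboratory results
#'
#' Biometric rows are typed "from physical examination"; laboratory rows are
#' typed Lab (32856); the `measurement_source_type_id` column distinguishes
#' the two source tables. Values outside the configured plausibility ranges
#' are excluded and logged with a reason, as are non-numeric values where a
#' number is required. Unmapped labels produce rows with
#' measurement_concept_id 0 and the raw label in the source value.
#'
#' @param biometrics,lab_results staging tables.
#' @param ledger annotated `mapping_ledger`.
#' @param ranges optional [plausibility_ranges()]; when NULL no outlier
#'   filtering happens at transform time.
#' @param person_map,visit_map source-id lookups.
#' @param seq an [id_sequence()].
#' @return list(MEASUREMENT, rejections) with
#'   `rejections` = data.frame(source, raw_label, value, reason).
#' @export
build_measurements <- function(biometrics, lab_results, ledger, ranges = NULL,
                               person_map, visit_map,
                               seq = id_sequence("MEASUREMENT")) {
  lookup_tab <- function(df, feature, unit_col = "unit") {
    if (!nrow(df)) return(NULL)
    key <- paste(feature, df$variable, df[[unit_col]])
    idx <- !duplicated(key)
    map <- do.call(rbind, lapply(which(idx), function(i) {
      lk <- ledger_lookup(ledger, feature, df$variable[i],
                          unit = if (feature == "laboratory")
                            df[[unit_col]][i] else NULL)
      data.frame(key = key[i], concept = lk$concept,
                 source_concept = lk$source_concept)
    }))
    map[match(key, map$key), ]
  }
  unit_concept <- function(units) {
    vapply(units, function(u) {
      if (is.na(u)) return(0)
      ledger_lookup(ledger, "unit", u)$concept
    }, numeric(1), USE.NAMES = FALSE)
  }
  visit_of <- function(refs) {
    out <- rep(NA_integer_, length(refs))
    known <- !is.na(refs) & refs %in% names(visit_map)
    out[known] <- unname(visit_map[refs[known]])
    # present-but-unresolvable references are kept as an impossible visit id
    # so referential conformance checks (or the loader) can surface them
    out[!is.na(refs) & !known] <- -1L
    out
  }

  parts <- list(); rej <- list()
  emit <- function(df, feature, type_concept, source_type) {
    if (is.null(df) || !nrow(df)) return()
    lk <- lookup_tab(df, feature)
    val <- suppressWarnings(as.numeric(df$value))
    reason <- rep(NA_character_, nrow(df))
    reason[is.na(val)] <- "non-numeric value"
    if (!is.null(ranges) && !is.null(ranges$measurement_ranges)) {
      mr <- ranges$measurement_ranges
      m <- match(lk$concept, mr$concept_id)
      oob <- !is.na(m) & !is.na(val) & (val < mr$low[m] | val > mr$high[m])
      reason[oob & is.na(reason)] <- "out of range"
    }
    keep <- is.na(reason)
    refs <- if (feature == "biometric") df$consultation_id else
      df$consultation_ref
    rows <- NULL
    if (any(keep)) {
      rows <- data.frame(
        measurement_id = next_ids(seq, sum(keep)),
        person_id = unname(person_map[df$patient_id[keep]]),
        measurement_concept_id = lk$concept[keep],
        measurement_date = as_iso_date(df$date[keep]),
        measurement_type_concept_id = type_concept,
        value_as_number = val[keep],
        unit_concept_id = unit_concept(df$unit[keep]),
        visit_occurrence_id = visit_of(refs[keep]),
        measurement_source_value = df$variable[keep],
        measurement_source_concept_id = lk$source_concept[keep],
        unit_source_value = df$unit[keep],
        measurement_source_type_id = source_type)
    }
    parts[[length(parts) + 1L]] <<- rows
    if (any(!keep))
      rej[[length(rej) + 1L]] <<- data.frame(
        source = source_type, raw_label = df$variable[!keep],
        value = df$value[!keep], reason = reason[!keep])
  }
  emit(biometrics, "biometric", PHYSICAL_EXAM_TYPE, "biometrics")
  emit(lab_results, "laboratory", LAB_TYPE, "laboratory")
  meas <- rbind_all(parts, NULL)
  rejections <- rbind_all(rej, data.frame(
    source = character(0), raw_label = character(0), value = character(0),
    reason = character(0)))
  list(MEASUREMENT = meas, rejections = rejections)
}

# -- drug exposures ---------------------------------------------------------

#' Build DRUG_EXPOSURE rows from CIP-coded prescriptions
#'
#' One row per prescription, carrying the RxNorm standard concept when the
#' two-hop CIP -> ATC -> RxNorm mapping succeeded, else concept 0 with the
#' CIP code preserved in drug_source_value. Dosage fields (days supply,
#' refills, quantity) are carried through. Prescriptions without a date get
#' null dates (flagged later by completeness checks).
#'
#' @param prescriptions staging table.
#' @param ledger annotated `mapping_ledger`.
#' @param person_map,visit_map source-id lookups.
#' @param seq an [id_sequence()].
#' @param exposure_end_rule see [era_config()].
#' @return data.frame of DRUG_EXPOSURE rows.
#' @export
build_drug_exposures <- function(prescriptions, ledger, person_map, visit_map,
                                 seq = id_sequence("DRUG_EXPOSURE"),
                                 exposure_end_rule = "start_plus_days_supply") {
  df <- prescriptions
  if (!nrow(df)) return(NULL)
  lk <- do.call(rbind, lapply(unique(df$cip), function(code) {
    l <- ledger_lookup(ledger, "drug", code)
    data.frame(cip = code, concept = l$concept,
               source_concept = l$source_concept)
  }))
  m <- lk[match(df$cip, lk$cip), ]
  start <- as_iso_date(df$date)
  ds <- suppressWarnings(as.integer(df$days_supply))
  end <- if (exposure_end_rule == "start_plus_days_supply")
    as.Date(ifelse(is.na(ds), start, start + pmax(ds - 1L, 0L)),
            origin = "1970-01-01") else start
  data.frame(
    drug_exposure_id = next_ids(seq, nrow(df)),
    person_id = unname(person_map[df$patient_id]),
    drug_concept_id = m$concept,
    drug_exposure_start_date = start, drug_exposure_end_date = end,
    drug_type_concept_id = EHR_TYPE,
    refills = suppressWarnings(as.integer(df$refills)),
    quantity = suppressWarnings(as.numeric(df$quantity)),
    days_supply = ds,
    visit_occurrence_id = unname(visit_map[df$consultation_id]),
    drug_source_value = df$cip, drug_source_concept_id = m$source_concept)
}

# -- notes ------------------------------------------------------------------

NOTE_CLASS_NAMES <- c(
  reason = "Reason for consultation note",
  interview = "Interview note",
  diagnosis = "Diagnosis note",
  referral = "Referral note",
  vaccination = "Vaccination note",
  supplementary = "Supplementary information note",
  history = "Medical history note",
  clinical_report = "Clinical report from external physician")

#' Build NOTE rows from the free-text items
#'
#' One row per free-text item; the note class concept encodes the item's
#' provenance (consultation reason, interview, diagnosis, referral,
#' vaccination, supplementary information, free-text medical history, or a
#' clinical report from an external specialist). Text is stored verbatim;
#' items with empty text are skipped with a log entry.
#'
#' @param notes staging notes table (columns patient_id, consultation_id,
#'   date, class, text).
#' @param store a `concept_store` holding the note-class concepts.
#' @param person_map,visit_map source-id lookups.
#' @param seq an [id_sequence()].
#' @return list(NOTE, skipped) where `skipped` logs empty-text items.
#' @export
build_notes <- function(notes, store, person_map, visit_map,
                        seq = id_sequence("NOTE")) {
  if (!nrow(notes)) return(list(NOTE = NULL, skipped = NULL))
  class_id <- vapply(NOTE_CLASS_NAMES, function(nm) {
    id <- store$concept$concept_id[store$concept$concept_name == nm]
    if (length(id)) id[1] else 0
  }, numeric(1))
  empty <- is.na(notes$text) | !nzchar(trimws(notes$text))
  skipped <- notes[empty, , drop = FALSE]
  keep <- notes[!empty, , drop = FALSE]
  if (!nrow(keep)) return(list(NOTE = NULL, skipped = skipped))
  vm <- rep(NA_integer_, nrow(keep))
  known <- !is.na(keep$consultation_id) &
    keep$consultation_id %in% names(visit_map)
  vm[known] <- unname(visit_map[keep$consultation_id[known]])
  rows <- data.frame(
    note_id = next_ids(seq, nrow(keep)),
    person_id = unname(person_map[keep$patient_id]),
    note_date = as_iso_date(keep$date),
    note_type_concept_id = EHR_TYPE,
    note_class_concept_id = unname(class_id[keep$class]),
    note_title = keep$class, note_text = keep$text,
    encoding_concept_id = 0, language_concept_id = 0,
    visit_occurrence_id = vm)
  list(NOTE = rows, skipped = skipped)
}

# -- observations -----------------------------------------------------------

#' Build OBSERVATION rows from ICD-10-coded medical histories
#'
#' One row per coded history item carrying the ICD-10 concept (standard in
#' the bundled vocabulary) or concept 0 with a conformance flag when the code
#' is syntactically invalid or unknown. Free-text histories are not routed
#' here; they become NOTE rows.
#'
#' @param coded_histories staging histories with `coded == TRUE`.
#' @param ledger annotated `mapping_ledger`.
#' @param person_map source-id lookup.
#' @param seq an [id_sequence()].
#' @return data.frame of OBSERVATION rows.
#' @export
build_observations <- function(coded_histories, ledger, person_map,
                               seq = id_sequence("OBSERVATION")) {
  df <- coded_histories[coded_histories$coded, , drop = FALSE]
  if (!nrow(df)) return(NULL)
  valid <- grepl("^[A-Z]\\d{2}(\\.\\d+)?$", df$icd10)
  concept <- numeric(nrow(df)); source_concept <- numeric(nrow(df))
  for (code in unique(df$icd10[valid])) {
    l <- ledger_lookup(ledger, "history_icd10", code)
    sel <- df$icd10 == code
    concept[sel] <- l$concept
    source_concept[sel] <- l$source_concept
  }
  data.frame(
    observation_id = next_ids(seq, nrow(df)),
    person_id = unname(person_map[df$patient_id]),
    observation_concept_id = concept,
    observation_date = as_iso_date(df$date),
    observation_type_concept_id = EHR_TYPE,
    value_as_string = NA_character_, visit_occurrence_id = NA_integer_,
    observation_source_value = df$icd10,
    observation_source_concept_id = source_concept)
}

# registration with the family physician, kept as a dated observation so the
# cutoff rule of the validation queries has a warehouse-side counterpart
build_registrations <- function(patients, person_map, store,
                                seq = id_sequence("OBSERVATION")) {
  if (!nrow(patients)) return(NULL)
  reg_concept <- register_local_concept(
    store, "registration with family physician", "Weda-registration",
    "Observation")
  data.frame(
    observation_id = next_ids(seq, nrow(patients)),
    person_id = unname(person_map[patients$patient_id]),
    observation_concept_id = reg_concept$concept_id,
    observation_date = as_iso_date(patients$registration_date),
    observation_type_concept_id = EHR_TYPE,
    value_as_string = NA_character_, visit_occurrence_id = NA_integer_,
    observation_source_value = patients$physician_id,
    observation_source_concept_id = reg_concept$concept_id)
}

# -- derived tables ---------------------------------------------------------

#' Derive OBSERVATION_PERIOD rows
#'
#' At most one period per person spanning `[earliest, latest]` of the
#' person's dated events (visits, measurements, drug exposures, notes,
#' observations). Persons without any dated event get no period.
#'
#' @param event_dates data.frame with columns `person_id`, `date`.
#' @param seq an [id_sequence()].
#' @return data.frame of OBSERVATION_PERIOD rows, ordered by person_id.
#' @export
derive_observation_periods <- function(event_dates,
                                       seq = id_sequence("OBSERVATION_PERIOD")) {
  ev <- event_dates[!is.na(event_dates$date) & !is.na(event_dates$person_id), ,
                    drop = FALSE]
  if (!nrow(ev)) return(NULL)
  sp <- split(as.numeric(ev$date), ev$person_id)
  pid <- as.integer(names(sp))
  ord <- order(pid)
  data.frame(
    observation_period_id = next_ids(seq, length(sp)),
    person_id = pid[ord],
    observation_period_start_date = as.Date(
      vapply(sp, min, numeric(1))[ord], origin = "1970-01-01"),
    observation_period_end_date = as.Date(
      vapply(sp, max, numeric(1))[ord], origin = "1970-01-01"),
    period_type_concept_id = EHR_TYPE)
}

#' Derive DRUG_ERA rows from drug exposures
#'
#' Exposures are resolved to ingredient level through the store's
#' "RxNorm has ingredient" links (a combination product yields one era
#' stream per ingredient, so eras can outnumber exposures; a drug concept
#' without ingredient links stands for itself). Per (person, ingredient),
#' exposures are sorted by start date and merged greedily: the next exposure
#' joins the current era when its start is on or before the era end plus the
#' persistence window. The era end is the maximum exposure end;
#' `gap_days` accumulates the uncovered days inside the era and
#' `drug_exposure_count` the number of merged exposures. Exposures with an
#' end before their start are excluded (plausibility-flagged), as are
#' unmapped exposures (concept 0).
#'
#' @param exposures DRUG_EXPOSURE rows.
#' @param store a `concept_store`.
#' @param cfg an [era_config()].
#' @param seq an [id_sequence()].
#' @return list(DRUG_ERA, excluded) where `excluded` logs skipped exposures.
#' @export
derive_drug_eras <- function(exposures, store, cfg = era_config(),
                             seq = id_sequence("DRUG_ERA")) {
  if (is.null(exposures) || !nrow(exposures))
    return(list(DRUG_ERA = NULL, excluded = NULL))
  bad <- !is.na(exposures$drug_exposure_end_date) &
    exposures$drug_exposure_end_date < exposures$drug_exposure_start_date
  excluded <- exposures[bad | exposures$drug_concept_id == 0, , drop = FALSE]
  ex <- exposures[!bad & exposures$drug_concept_id != 0, , drop = FALSE]
  if (!nrow(ex)) return(list(DRUG_ERA = NULL, excluded = excluded))

  # ingredient resolution
  rels <- store$concept_relationship
  ing <- rels[rels$relationship_id == "RxNorm has ingredient", , drop = FALSE]
  resolve <- function(cid) {
    hits <- ing$concept_id_2[ing$concept_id_1 == cid]
    if (length(hits)) hits else cid
  }
  drug_ids <- unique(ex$drug_concept_id)
  ing_map <- stats::setNames(lapply(drug_ids, resolve), drug_ids)

  counts <- lengths(ing_map)[as.character(ex$drug_concept_id)]
  idx <- rep(seq_len(nrow(ex)), counts)
  s <- data.frame(
    person_id = ex$person_id[idx],
    ingredient = unlist(ing_map[as.character(ex$drug_concept_id)],
                        use.names = FALSE),
    start = ex$drug_exposure_start_date[idx],
    end = ex$drug_exposure_end_date[idx])
  s <- s[order(s$person_id, s$ingredient, s$start, s$end), , drop = FALSE]

  out <- list()
  key <- paste(s$person_id, s$ingredient)
  groups <- split(seq_len(nrow(s)), factor(key, levels = unique(key)))
  for (rows_k in groups) {
    grp <- s[rows_k, , drop = FALSE]
    era_start <- grp$start[1]; era_end <- grp$end[1]
    n_exp <- 1L; gaps <- 0L
    flush <- function() out[[length(out) + 1L]] <<- data.frame(
      person_id = grp$person_id[1], drug_concept_id = grp$ingredient[1],
      drug_era_start_date = era_start, drug_era_end_date = era_end,
      drug_exposure_count = n_exp, gap_days = gaps)
    for (j in seq_len(nrow(grp))[-1]) {
      if (as.numeric(grp$start[j] - era_end) <= cfg$persistence_window) {
        gaps <- gaps + max(0L, as.integer(grp$start[j] - era_end) - 1L)
        era_end <- max(era_end, grp$end[j])
        n_exp <- n_exp + 1L
      } else {
        flush()
        era_start <- grp$start[j]; era_end <- grp$end[j]
        n_exp <- 1L; gaps <- 0L
      }
    }
    flush()
  }
  eras <- do.call(rbind, out)
  eras <- cbind(drug_era_id = next_ids(seq, nrow(eras)), eras)
  list(DRUG_ERA = eras, excluded = excluded)
}

# -- orchestration ----------------------------------------------------------

#' Run the full structural transform
#'
#' Staging + annotated ledger + concept store -> the complete set of CDM
#' subset tables (including the vocabulary tables as they stand after local
#' concept registration), with rejection logs making every row drop
#' attributable.
#'
#' @param staging a `staging_store`.
#' @param ledger an annotated `mapping_ledger`.
#' @param store a `concept_store`.
#' @param ranges optional [plausibility_ranges()] for transform-time outlier
#'   filtering.
#' @param era an [era_config()].
#' @return list with `tables` (named list of CDM data.frames), `logs`
#'   (rejections, skipped notes, excluded exposures, warnings) and
#'   `person_map`.
#' @export
build_cdm <- function(staging, ledger, store, ranges = NULL,
                      era = era_config()) {
  demo <- build_demographics(staging, ledger)
  provider_of_person <- stats::setNames(demo$PERSON$provider_id,
                                        demo$PERSON$person_id)
  visits <- build_visits(staging$consultations, demo$person_map,
                         provider_of_person)
  meas <- build_measurements(staging$biometrics, staging$lab_results, ledger,
                             ranges, demo$person_map, visits$visit_map)
  rx <- build_drug_exposures(staging$prescriptions, ledger, demo$person_map,
                             visits$visit_map,
                             exposure_end_rule = era$exposure_end_rule)
  notes <- build_notes(staging$notes, store, demo$person_map,
                       visits$visit_map)
  obs_seq <- id_sequence("OBSERVATION")
  obs <- build_observations(staging$histories, ledger, demo$person_map,
                            seq = obs_seq)
  reg <- build_registrations(staging$patients, demo$person_map, store,
                             seq = obs_seq)
  observations <- rbind_all(list(obs, reg), NULL)

  event_dates <- rbind(
    data.frame(person_id = visits$VISIT_OCCURRENCE$person_id,
               date = visits$VISIT_OCCURRENCE$visit_start_date),
    if (!is.null(meas$MEASUREMENT)) data.frame(
      person_id = meas$MEASUREMENT$person_id,
      date = meas$MEASUREMENT$measurement_date),
    if (!is.null(rx)) data.frame(
      person_id = rx$person_id, date = rx$drug_exposure_start_date),
    if (!is.null(notes$NOTE)) data.frame(
      person_id = notes$NOTE$person_id, date = notes$NOTE$note_date),
    if (!is.null(observations)) data.frame(
      person_id = observations$person_id,
      date = observations$observation_date))
  periods <- derive_observation_periods(event_dates)
  eras <- derive_drug_eras(rx, store, era)

  tables <- list(
    VOCABULARY = store$vocabulary, CONCEPT = store$concept,
    CONCEPT_RELATIONSHIP = store$concept_relationship,
    LOCATION = demo$LOCATION, CARE_SITE = demo$CARE_SITE,
    PROVIDER = demo$PROVIDER, PERSON = demo$PERSON, DEATH = demo$DEATH,
    OBSERVATION_PERIOD = periods,
    VISIT_OCCURRENCE = visits$VISIT_OCCURRENCE,
    MEASUREMENT = meas$MEASUREMENT, DRUG_EXPOSURE = rx,
    NOTE = notes$NOTE, OBSERVATION = observations,
    DRUG_ERA = eras$DRUG_ERA)
  tables <- Filter(Negate(is.null), tables)
  list(tables = tables,
       logs = list(measurement_rejections = meas$rejections,
                   skipped_notes = notes$skipped,
                   excluded_exposures = eras$excluded,
                   warnings = demo$warnings),
       person_map = demo$person_map)
}
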