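# Staging extraction: parse the per-patient XML export into normalized
# staging tables (raw values untouched) and profile them. The profiling step
# is a minimal stand-in for an OHDSI-style source scan: per-field inferred
# type, null fraction, distinct counts and top-k value frequencies.

staging_templates <- function() {
  list(
    patients = data.frame(
      patient_id = character(0), sex = character(0),
      year_of_birth = character(0), town = character(0),
      country = character(0), physician_id = character(0),
      registration_date = character(0), file = character(0)),
    consultations = data.frame(
      consultation_id = character(0), patient_id = character(0),
      date = character(0), date_valid = logical(0)),
    biometrics = data.frame(
      patient_id = character(0), consultation_id = character(0),
      date = character(0), variable = character(0), value = character(0),
      unit = character(0)),
    lab_results = data.frame(
      patient_id = character(0), laboratory = character(0),
      date = character(0), consultation_ref = character(0),
      variable = character(0), value = character(0), unit = character(0)),
    prescriptions = data.frame(
      patient_id = character(0), consultation_id = character(0),
      date = character(0), cip = character(0), days_supply = character(0),
      refills = character(0), quantity = character(0)),
    histories = data.frame(
      patient_id = character(0), coded = logical(0), icd10 = character(0),
      text = character(0), date = character(0)),
    notes = data.frame(
      patient_id = character(0), consultation_id = character(0),
      date = character(0), class = character(0), text = character(0)),
    addresses = data.frame(
      patient_id = character(0), line = character(0), town = character(0),
      postal_code = character(0), country = character(0)),
    deaths = data.frame(
      patient_id = character(0), date = character(0)),
    providers = data.frame(provider_id = character(0))
  )
}

xattr <- function(nodes, a) xml2::xml_attr(nodes, a)

#' Parse one patient XML document into staging records
#'
#' Each of the four consultation steps lands in its staging entity: the
#' free-text reason, interview, diagnosis, referral, vaccination and
#' supplementary texts become `notes` rows (with a provenance class);
#' structured biometrics become `biometrics` rows; prescriptions become
#' `prescriptions` rows. Laboratory result sets, medical histories, the
#' address and any death record land in their own tables. Raw values are
#' never altered: dates stay as strings with a validity flag.
#'
#' @param path path to one patient XML document.
#' @return named list of staging data.frames (one element per entity) with a
#'   `warnings` attribute for malformed optional elements.
#' @export
parse_patient_document <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    etl_stop("parse", "cannot parse XML document '%s': %s",
             path, conditionMessage(e)))
  root <- xml2::xml_name(doc)
  if (root != "patient-export")
    etl_stop("parse", "document '%s' has unexpected root element <%s>",
             path, root)
  ver <- xml2::xml_attr(doc, "schema-version")
  if (is.na(ver) || ver != EXPORT_SCHEMA_VERSION)
    etl_stop("schema", "document '%s' declares unknown schema version '%s'",
             path, ver)
  pat <- xml2::xml_find_first(doc, "./patient")
  if (inherits(pat, "xml_missing"))
    etl_stop("parse", "document '%s' has no <patient> element", path)
  pid <- xml2::xml_attr(pat, "id")
  warnings <- character(0)

  demo <- xml2::xml_find_first(pat, "./demographics")
  reg <- xml2::xml_find_first(pat, "./registration")
  out <- staging_templates()

  out$patients <- data.frame(
    patient_id = pid,
    sex = xml2::xml_attr(demo, "sex"),
    year_of_birth = xml2::xml_attr(demo, "year-of-birth"),
    town = xml2::xml_attr(demo, "town"),
    country = xml2::xml_attr(demo, "country"),
    physician_id = xml2::xml_attr(reg, "physician"),
    registration_date = xml2::xml_attr(reg, "date"),
    file = path)

  death <- xml2::xml_find_first(pat, "./death")
  if (!inherits(death, "xml_missing"))
    out$deaths <- data.frame(patient_id = pid,
                             date = xml2::xml_attr(death, "date"))

  cons <- xml2::xml_find_all(pat, "./consultations/consultation")
  if (length(cons)) {
    cdates <- xattr(cons, "date")
    out$consultations <- data.frame(
      consultation_id = xattr(cons, "id"), patient_id = pid,
      date = cdates, date_valid = is_iso_date_string(cdates))
    note_rows <- list(); bio_rows <- list(); rx_rows <- list()
    for (i in seq_along(cons)) {
      cn <- cons[[i]]; cid <- xml2::xml_attr(cn, "id")
      cdate <- cdates[i]
      txt <- function(xpath, class) {
        nodes <- xml2::xml_find_all(cn, xpath)
        if (!length(nodes)) return(NULL)
        data.frame(patient_id = pid, consultation_id = cid, date = cdate,
                   class = class, text = xml2::xml_text(nodes))
      }
      note_rows <- c(note_rows, list(
        txt("./reason", "reason"), txt("./interview", "interview"),
        txt("./outcome/diagnosis", "diagnosis"),
        txt("./outcome/referral", "referral"),
        txt("./outcome/vaccination", "vaccination"),
        txt("./outcome/supplementary", "supplementary")))
      bios <- xml2::xml_find_all(cn, "./examination/biometric")
      if (length(bios))
        bio_rows[[length(bio_rows) + 1L]] <- data.frame(
          patient_id = pid, consultation_id = cid, date = cdate,
          variable = xattr(bios, "variable"), value = xattr(bios, "value"),
          unit = xattr(bios, "unit"))
      rx <- xml2::xml_find_all(cn, "./outcome/prescription")
      if (length(rx))
        rx_rows[[length(rx_rows) + 1L]] <- data.frame(
          patient_id = pid, consultation_id = cid, date = cdate,
          cip = xattr(rx, "cip"), days_supply = xattr(rx, "days-supply"),
          refills = xattr(rx, "refills"), quantity = xattr(rx, "quantity"))
    }
    out$notes <- rbind_all(note_rows, out$notes)
    out$biometrics <- rbind_all(bio_rows, out$biometrics)
    out$prescriptions <- rbind_all(rx_rows, out$prescriptions)
  }

  hist <- xml2::xml_find_all(pat, "./medical-history/item")
  if (length(hist)) {
    coded <- xattr(hist, "coded") == "true"
    out$histories <- data.frame(
      patient_id = pid, coded = coded, icd10 = xattr(hist, "icd10"),
      text = ifelse(coded, NA_character_, xml2::xml_text(hist)),
      date = xattr(hist, "date"))
    ft <- out$histories[!coded, , drop = FALSE]
    if (nrow(ft))
      out$notes <- rbind(out$notes, data.frame(
        patient_id = pid, consultation_id = NA_character_, date = ft$date,
        class = "history", text = ft$text))
  }

  sets <- xml2::xml_find_all(pat, "./lab-results/result-set")
  if (length(sets)) {
    lab_rows <- list()
    for (s in seq_along(sets)) {
      sn <- sets[[s]]
      res <- xml2::xml_find_all(sn, "./result")
      if (!length(res)) {
        warnings <- c(warnings, sprintf(
          "empty result-set on %s for %s", xml2::xml_attr(sn, "date"), pid))
        next
      }
      lab_rows[[length(lab_rows) + 1L]] <- data.frame(
        patient_id = pid, laboratory = xml2::xml_attr(sn, "laboratory"),
        date = xml2::xml_attr(sn, "date"),
        consultation_ref = xml2::xml_attr(sn, "consultation-ref"),
        variable = xattr(res, "variable"), value = xattr(res, "value"),
        unit = xattr(res, "unit"))
    }
    out$lab_results <- rbind_all(lab_rows, out$lab_results)
  }

  reps <- xml2::xml_find_all(pat, "./clinical-reports/report")
  if (length(reps))
    out$notes <- rbind(out$notes, data.frame(
      patient_id = pid, consultation_id = NA_character_,
      date = xattr(reps, "date"), class = "clinical_report",
      text = xml2::xml_text(reps)))

  addr <- xml2::xml_find_all(pat, "./addresses/address")
  if (length(addr))
    out$addresses <- data.frame(
      patient_id = pid, line = xattr(addr, "line"),
      town = xattr(addr, "town"), postal_code = xattr(addr, "postal-code"),
      country = xattr(addr, "country"))

  phys <- out$patients$physician_id
  if (!is.na(phys)) out$providers <- data.frame(provider_id = phys)
  attr(out, "warnings") <- warnings
  out
}

#' Extract a whole export directory into a staging store
#'
#' Parses every patient document and unions the per-document staging records.
#' Atomic: a corrupt file aborts the whole extraction with an error naming
#' the file, and duplicate patient identifiers are rejected.
#'
#' @param dir directory containing `*.xml` patient documents.
#' @return a `staging_store`: named list of staging data.frames plus a
#'   `warnings` attribute.
#' @export
extract_all <- function(dir) {
  if (!dir.exists(dir)) etl_stop("input", "directory '%s' does not exist", dir)
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  if (!length(files))
    etl_stop("input", "directory '%s' contains no patient documents", dir)
  parts <- lapply(files, parse_patient_document)
  tmpl <- staging_templates()
  store <- lapply(names(tmpl), function(tab)
    rbind_all(lapply(parts, `[[`, tab), tmpl[[tab]]))
  names(store) <- names(tmpl)
  dup <- store$patients$patient_id[duplicated(store$patients$patient_id)]
  if (length(dup))
    etl_stop("integrity", "duplicate patient identifier(s): %s",
             paste(unique(dup), collapse = ", "))
  for (pid_tab in c("consultations", "biometrics", "lab_results",
                    "prescriptions", "histories", "notes", "addresses",
                    "deaths")) {
    orphan <- setdiff(store[[pid_tab]]$patient_id, store$patients$patient_id)
    if (length(orphan))
      etl_stop("integrity", "%s rows reference unknown patient(s): %s",
               pid_tab, paste(orphan, collapse = ", "))
  }
  dupc <- store$consultations$consultation_id[
    duplicated(store$consultations$consultation_id)]
  if (length(dupc))
    etl_stop("integrity", "duplicate consultation identifier(s): %s",
             paste(unique(dupc), collapse = ", "))
  store$providers <- data.frame(
    provider_id = sort(unique(store$providers$provider_id)))
  attr(store, "warnings") <- unlist(lapply(parts, attr, "warnings"))
  class(store) <- "staging_store"
  store
}

#' @export
print.staging_store <- function(x, ...) {
  cat("<staging_store>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Profile a staging store
#'
#' Produces a scan report covering every table and field: inferred type
#' (numeric, date or text), null fraction, distinct-value count and the
#' top-k value frequencies. Empty fields yield a null fraction of 1.
#'
#' @param store a `staging_store` from [extract_all()].
#' @param top_k how many most-frequent values to keep per field.
#' @return a `scan_report` data.frame (one row per table/field) with a
#'   `frequencies` attribute (named list of top-k tables).
#' @export
profile_staging <- function(store, top_k = 10) {
  if (!inherits(store, "staging_store"))
    etl_stop("input", "profile_staging() expects a staging_store")
  rows <- list(); freqs <- list()
  for (tab in names(store)) {
    df <- store[[tab]]
    for (field in names(df)) {
      v <- df[[field]]
      chr <- as.character(v)
      isna <- is.na(chr) | chr == ""
      nonnull <- chr[!isna]
      type <- if (!length(nonnull)) "empty"
        else if (is.logical(v)) "logical"
        else if (all(is_iso_date_string(nonnull))) "date"
        else if (!anyNA(suppressWarnings(as.numeric(nonnull)))) "numeric"
        else "text"
      tf <- sort(table(nonnull), decreasing = TRUE)
      tf <- utils::head(tf, top_k)
      key <- paste(tab, field, sep = ".")
      freqs[[key]] <- data.frame(value = names(tf),
                                 count = as.integer(tf))
      rows[[key]] <- data.frame(
        table = tab, field = field, type = type,
        n = length(chr),
        null_fraction = if (length(chr)) mean(isna) else 1.0,
        n_distinct = length(unique(nonnull)))
    }
  }
  rep <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(rep, "frequencies") <- freqs
  class(rep) <- c("scan_report", "data.frame")
  rep
}
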