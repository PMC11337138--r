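# Synthetic source-EHR generator: per-patient hierarchical XML exports in the
# style of a French primary-care patient-monitoring system, plus a
# ground-truth manifest so every downstream ETL stage can be tested against
# known counts. The XML schema is this package's own (documented in
# inst/extdata/export-schema.md, versioned via the schema-version attribute).

EXPORT_SCHEMA_VERSION <- "1.0"

# -- default catalogs -------------------------------------------------------

#' Default laboratory vocabulary variants
#'
#' Each canonical analyte carries the laboratory-specific spellings and units
#' under which different medical laboratories report it (e.g. "Creatinine"
#' in umol/L from one laboratory, "create" in mg/L from another). Values are
#' drawn from a normal law with the variant's mean/sd, in the variant's unit.
#'
#' @return named list: canonical analyte -> data.frame(label, unit, mean, sd).
#' @export
default_lab_variants <- function() {
  list(
    potassium = data.frame(
      label = c("Potassium", "potassium (mmol/L)", "K+"),
      unit = c("mmol/L", "mmol/L", "mmol/L"),
      mean = 4.2, sd = 0.4),
    sodium = data.frame(
      label = c("Sodium", "Na+"),
      unit = c("mmol/L", "mmol/L"),
      mean = 140, sd = 3),
    creatinine = data.frame(
      label = c("Creatinine", "create"),
      unit = c("umol/L", "mg/L"),
      mean = c(80, 9), sd = c(15, 1.7)),
    crp = data.frame(
      label = c("CRP", "C-reactive protein"),
      unit = c("mg/L", "mg/L"),
      mean = 5, sd = 4),
    hemoglobin = data.frame(
      label = c("Hemoglobine", "Hb"),
      unit = c("g/dL", "g/dL"),
      mean = 14, sd = 1.3),
    glucose = data.frame(
      label = c("Glycemie", "Glucose"),
      unit = c("mmol/L", "mmol/L"),
      mean = 5.4, sd = 0.9)
  )
}

#' Default prescription drug catalog
#'
#' CIP presentation codes (the French national drug code) with their ATC
#' parents; every default entry has a complete CIP -> ATC -> RxNorm chain in
#' the bundled vocabulary fixture, so a defect-free build maps fully.
#'
#' @return data.frame with columns cip, name, atc.
#' @export
default_cip_catalog <- function() {
  data.frame(
    cip = c("3400930000011", "3400930000028", "3400930000035",
            "3400930000042", "3400930000059", "3400930000066",
            "3400930000073", "3400930000080", "3400930000097"),
    name = c("paracetamol", "amoxicillin", "lisinopril", "metformin",
             "simvastatin", "amlodipine", "levothyroxine", "ibuprofen",
             "amoxicillin-clavulanate"),
    atc = c("N02BE01", "J01CA04", "C09AA03", "A10BA02",
            "C10AA01", "C08CA01", "H03AA01", "M01AE01", "J01CR02")
  )
}

# Biometric variables as the physicians type them (French labels), with the
# law used to draw values.
default_biometric_catalog <- function() {
  data.frame(
    variable = c("Poids", "Taille", "TA systolique", "TA diastolique",
                 "Frequence cardiaque", "IMC"),
    unit = c("kg", "cm", "mmHg", "mmHg", "/min", "kg/m2"),
    mean = c(72, 168, 128, 78, 72, 25.5),
    sd = c(15, 10, 15, 10, 11, 4)
  )
}

default_icd10_codes <- function() {
  c("E11", "I10", "J45", "E78", "F32", "M54", "K21", "E03")
}

FREE_TEXT <- list(
  reason = c("Douleur abdominale", "Fievre depuis 2 jours",
             "Renouvellement d'ordonnance", "Toux persistante",
             "Controle annuel", "Douleur lombaire", "Cephalees", "Fatigue",
             "Suivi diabete", "Vaccination"),
  interview = c("Examen clinique sans particularite",
                "Douleur a la palpation", "Auscultation pulmonaire libre",
                "Patient fatigue, pas de signe de gravite",
                "Symptomes depuis une semaine", "Etat general conserve"),
  diagnosis = c("Syndrome viral", "Lombalgie commune", "Gastro-enterite",
                "Hypertension arterielle", "Bronchite aigue", "Anxiete",
                "Infection urinaire"),
  referral = c("Adresse au cardiologue pour avis",
               "Adresse au dermatologue", "Bilan radiologique demande"),
  vaccination = c("Vaccin antigrippal effectue", "Rappel DTP effectue"),
  history_free = c("diabetique depuis 2004", "appendicectomie dans l'enfance",
                   "tabagisme sevre", "allergie penicilline",
                   "fracture du poignet en 2010"),
  clinical_report = c("Compte rendu de consultation cardiologique : examen normal",
                      "Compte rendu ophtalmologique : fond d'oeil normal",
                      "Compte rendu de radiographie : pas d'anomalie decelable"),
  supplementary = c("Informations complementaires transmises par le patient",
                    "Document administratif ajoute au dossier"),
  towns = c("Wattrelos", "Roubaix", "Tourcoing", "Lille", "Leers", "Croix"),
  streets = c("rue des Lilas", "avenue de la Republique", "rue Pasteur",
              "boulevard Gambetta", "rue Jean Jaures", "place de la Mairie")
)

# -- configuration ----------------------------------------------------------

#' Configuration for the synthetic source-EHR export generator
#'
#' Defaults reproduce the event rates of a two-decade, ~18,000-patient
#' primary-care warehouse scaled to the requested number of patients: a mean
#' of 32.2 consultations per patient, 1.56 prescriptions per consultation,
#' 0.3 biometric measurements per consultation, ~8.5 laboratory panels per
#' patient, a 3.6% coded (vs free-text) medical-history rate, and a 2.3%
#' death rate, over a 2013-01-01 to 2021-06-30 observation window.
#'
#' @param n_patients number of patient documents to generate (>= 1).
#' @param date_range character or Date vector of length 2, start < end.
#' @param n_physicians number of family physicians at the health center.
#' @param mean_visits_per_patient Poisson mean of the per-patient
#'   consultation count.
#' @param lab_vocabulary_variants see [default_lab_variants()].
#' @param cip_catalog see [default_cip_catalog()]; every CIP code must carry
#'   an ATC parent.
#' @param icd10_history_rate probability that a medical-history item is
#'   ICD-10-coded rather than free text.
#' @param death_rate probability that a patient has a death record.
#' @param mean_prescriptions_per_visit Poisson mean per consultation.
#' @param biometric_visit_rate probability a consultation records biometrics.
#' @param mean_lab_panels_per_patient Poisson mean of laboratory result sets.
#' @param n_laboratories number of external laboratories (each uses one
#'   spelling/unit variant per analyte).
#' @param missing_field_rates named list of per-field missingness
#'   probabilities (supported: `town`, `interview`).
#' @param icd10_codes pool of ICD-10 codes used for coded histories.
#' @param seed integer RNG seed; identical config + seed gives byte-identical
#'   exports.
#' @return a validated `generator_config` object.
#' @export
generator_config <- function(n_patients = 500,
                             date_range = c("2013-01-01", "2021-06-30"),
                             n_physicians = 8,
                             mean_visits_per_patient = 32.2,
                             lab_vocabulary_variants = default_lab_variants(),
                             cip_catalog = default_cip_catalog(),
                             icd10_history_rate = 0.036,
                             death_rate = 0.023,
                             mean_prescriptions_per_visit = 1.56,
                             biometric_visit_rate = 0.15,
                             mean_lab_panels_per_patient = 8.5,
                             n_laboratories = 3,
                             missing_field_rates = list(town = 0.05,
                                                        interview = 0.10),
                             icd10_codes = default_icd10_codes(),
                             seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    date_range = as_iso_date(as.character(date_range)),
    n_physicians = as.integer(n_physicians),
    mean_visits_per_patient = mean_visits_per_patient,
    lab_vocabulary_variants = lab_vocabulary_variants,
    cip_catalog = cip_catalog,
    icd10_history_rate = icd10_history_rate,
    death_rate = death_rate,
    mean_prescriptions_per_visit = mean_prescriptions_per_visit,
    biometric_visit_rate = biometric_visit_rate,
    mean_lab_panels_per_patient = mean_lab_panels_per_patient,
    n_laboratories = as.integer(n_laboratories),
    missing_field_rates = missing_field_rates,
    icd10_codes = icd10_codes,
    biometric_catalog = default_biometric_catalog(),
    mean_history_items = 3.5,
    mean_clinical_reports = 0.5,
    diagnosis_rate = 0.5,
    referral_rate = 0.10,
    vaccination_rate = 0.05,
    supplementary_rate = 0.02,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 1)
    etl_stop("config", "invalid configuration field 'n_patients': must be >= 1")
  if (length(cfg$date_range) != 2 || anyNA(cfg$date_range) ||
      cfg$date_range[1] >= cfg$date_range[2])
    etl_stop("config",
             "invalid configuration field 'date_range': need start < end")
  if (is.na(cfg$n_physicians) || cfg$n_physicians < 1)
    etl_stop("config", "invalid configuration field 'n_physicians'")
  if (cfg$mean_visits_per_patient < 0)
    etl_stop("config",
             "invalid configuration field 'mean_visits_per_patient': must be >= 0")
  probs <- c(icd10_history_rate = cfg$icd10_history_rate,
             death_rate = cfg$death_rate,
             biometric_visit_rate = cfg$biometric_visit_rate,
             diagnosis_rate = cfg$diagnosis_rate,
             referral_rate = cfg$referral_rate,
             vaccination_rate = cfg$vaccination_rate)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad))
    etl_stop("config", "invalid configuration field '%s': not a probability",
             bad[1])
  cat_ <- cfg$cip_catalog
  if (!all(c("cip", "name", "atc") %in% names(cat_)))
    etl_stop("config",
             "invalid configuration field 'cip_catalog': needs cip/name/atc")
  if (any(is.na(cat_$atc) | !nzchar(cat_$atc)))
    etl_stop("config",
             "invalid configuration field 'cip_catalog': every CIP code needs an ATC parent")
  for (an in names(cfg$lab_vocabulary_variants)) {
    v <- cfg$lab_vocabulary_variants[[an]]
    if (!all(c("label", "unit", "mean", "sd") %in% names(v)) || nrow(v) < 1)
      etl_stop("config",
               "invalid configuration field 'lab_vocabulary_variants': analyte '%s'",
               an)
  }
  invisible(cfg)
}

# -- generation -------------------------------------------------------------

rdate <- function(n, from, to) {
  from + floor(stats::runif(n) * (as.numeric(to - from) + 1))
}

#' Generate a synthetic per-patient XML export with a ground-truth manifest
#'
#' Writes one XML document per patient (consultations in four steps: free-text
#' reason, free-text interview, structured biometrics, outcome with optional
#' diagnosis text / CIP-coded prescriptions / referral and vaccination notes;
#' plus laboratory result sets with laboratory-specific spellings, partly
#' coded medical histories, addresses and death records) and a JSON manifest
#' whose counts equal the written content exactly.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if absent).
#' @return list with elements `export` (a `source_export`: directory, files,
#'   schema version) and `manifest` (a `ground_truth_manifest`).
#' @export
generate_export <- function(config, dir = tempfile("weda-export-")) {
  validate_generator_config(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)

  physicians <- sprintf("DR%03d", seq_len(config$n_physicians))
  start <- config$date_range[1]; end <- config$date_range[2]

  # shared address pool so that distinct patients share locations
  n_addr_pool <- max(1L, ceiling(config$n_patients * 0.6))
  addr_pool <- data.frame(
    line = paste(sample(1:120, n_addr_pool, replace = TRUE),
                 sample(FREE_TEXT$streets, n_addr_pool, replace = TRUE)),
    town = sample(FREE_TEXT$towns, n_addr_pool, replace = TRUE),
    postal_code = sample(c("59150", "59100", "59200", "59000", "59115"),
                         n_addr_pool, replace = TRUE),
    country = "France"
  )

  analytes <- names(config$lab_vocabulary_variants)
  bio_cat <- config$biometric_catalog

  files <- character(config$n_patients)
  truth_pat <- vector("list", config$n_patients)
  truth_cons <- vector("list", config$n_patients)
  truth_rx <- vector("list", config$n_patients)
  truth_lab <- vector("list", config$n_patients)
  truth_bio <- vector("list", config$n_patients)
  truth_hist <- vector("list", config$n_patients)
  truth_rep <- vector("list", config$n_patients)
  n_notes_total <- 0L

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("pat-%06d", i)
    phys <- sample(physicians, 1)
    sex <- sample(c("M", "F"), 1, prob = c(0.49, 0.51))
    registration <- rdate(1, start, end - 30)
    # born no later than the registration year: the record stays
    # chronologically consistent by construction
    yob <- sample(1920:as.integer(format(registration, "%Y")), 1)
    dead <- stats::runif(1) < config$death_rate
    death_date <- if (dead) rdate(1, registration, end) else as.Date(NA)
    horizon <- if (dead) death_date else end

    addr_idx <- sample(n_addr_pool, 1)
    addr <- addr_pool[addr_idx, ]
    town <- if (stats::runif(1) < (config$missing_field_rates$town %||% 0))
      NA_character_ else addr$town

    n_visits <- stats::rpois(1, config$mean_visits_per_patient)
    visit_dates <- if (n_visits > 0)
      sort(rdate(n_visits, registration, horizon)) else as.Date(character(0))
    cons_ids <- if (n_visits > 0)
      sprintf("%s-c%04d", pid, seq_len(n_visits)) else character(0)

    lines <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      sprintf("<patient-export schema-version=\"%s\">", EXPORT_SCHEMA_VERSION),
      sprintf("  <patient id=\"%s\">", pid),
      sprintf("    <demographics sex=\"%s\" year-of-birth=\"%d\"%s country=\"France\"/>",
              sex, yob,
              if (is.na(town)) "" else sprintf(" town=\"%s\"", xml_escape(town))),
      sprintf("    <registration physician=\"%s\" date=\"%s\"/>",
              phys, fmt_date(registration))
    )
    if (dead)
      lines <- c(lines, sprintf("    <death date=\"%s\"/>", fmt_date(death_date)))

    # medical histories: a small fraction ICD-10-coded, the rest free text
    n_hist <- stats::rpois(1, config$mean_history_items)
    hist_rows <- NULL
    if (n_hist > 0) {
      hdates <- rdate(n_hist, registration, horizon)
      coded <- stats::runif(n_hist) < config$icd10_history_rate
      codes <- sample(config$icd10_codes, n_hist, replace = TRUE)
      texts <- sample(FREE_TEXT$history_free, n_hist, replace = TRUE)
      lines <- c(lines, "    <medical-history>")
      for (h in seq_len(n_hist)) {
        if (coded[h]) {
          lines <- c(lines, sprintf(
            "      <item coded=\"true\" icd10=\"%s\" date=\"%s\"/>",
            codes[h], fmt_date(hdates[h])))
        } else {
          lines <- c(lines, sprintf(
            "      <item coded=\"false\" date=\"%s\">%s</item>",
            fmt_date(hdates[h]), xml_escape(texts[h])))
          n_notes_total <- n_notes_total + 1L
        }
      }
      lines <- c(lines, "    </medical-history>")
      hist_rows <- data.frame(patient_id = pid, coded = coded,
                              icd10 = ifelse(coded, codes, NA_character_),
                              date = fmt_date(hdates))
    }

    # consultations, four steps each
    rx_rows <- NULL; bio_rows <- NULL
    lines <- c(lines, "    <consultations>")
    for (v in seq_len(n_visits)) {
      cid <- cons_ids[v]; cdate <- visit_dates[v]
      lines <- c(lines, sprintf("      <consultation id=\"%s\" date=\"%s\">",
                                cid, fmt_date(cdate)))
      lines <- c(lines, sprintf("        <reason>%s</reason>",
                                xml_escape(sample(FREE_TEXT$reason, 1))))
      n_notes_total <- n_notes_total + 1L
      if (stats::runif(1) >= (config$missing_field_rates$interview %||% 0)) {
        lines <- c(lines, sprintf("        <interview>%s</interview>",
                                  xml_escape(sample(FREE_TEXT$interview, 1))))
        n_notes_total <- n_notes_total + 1L
      }
      if (stats::runif(1) < config$biometric_visit_rate) {
        k <- sample(2:3, 1)
        rows <- bio_cat[sample(nrow(bio_cat), k), ]
        vals <- round_half_up(stats::rnorm(k, rows$mean, rows$sd), 1)
        vals <- pmax(vals, 0.1)
        lines <- c(lines, "        <examination>")
        lines <- c(lines, sprintf(
          "          <biometric variable=\"%s\" value=\"%s\" unit=\"%s\"/>",
          xml_escape(rows$variable), sprintf("%.1f", vals), rows$unit))
        lines <- c(lines, "        </examination>")
        bio_rows <- rbind(bio_rows, data.frame(
          patient_id = pid, consultation_id = cid, date = fmt_date(cdate),
          variable = rows$variable, value = vals, unit = rows$unit))
      }
      out_lines <- character(0)
      if (stats::runif(1) < config$diagnosis_rate) {
        out_lines <- c(out_lines, sprintf(
          "          <diagnosis>%s</diagnosis>",
          xml_escape(sample(FREE_TEXT$diagnosis, 1))))
        n_notes_total <- n_notes_total + 1L
      }
      n_rx <- stats::rpois(1, config$mean_prescriptions_per_visit)
      if (n_rx > 0) {
        drows <- config$cip_catalog[
          sample(nrow(config$cip_catalog), n_rx, replace = TRUE), ]
        ds <- sample(c(7L, 14L, 28L, 30L, 90L), n_rx, replace = TRUE)
        rf <- sample(0:3, n_rx, replace = TRUE)
        qt <- sample(1:3, n_rx, replace = TRUE)
        out_lines <- c(out_lines, sprintf(
          "          <prescription cip=\"%s\" days-supply=\"%d\" refills=\"%d\" quantity=\"%d\"/>",
          drows$cip, ds, rf, qt))
        rx_rows <- rbind(rx_rows, data.frame(
          patient_id = pid, consultation_id = cid, date = fmt_date(cdate),
          cip = drows$cip, name = drows$name, atc = drows$atc,
          days_supply = ds, refills = rf, quantity = qt))
      }
      if (stats::runif(1) < config$referral_rate) {
        out_lines <- c(out_lines, sprintf(
          "          <referral>%s</referral>",
          xml_escape(sample(FREE_TEXT$referral, 1))))
        n_notes_total <- n_notes_total + 1L
      }
      if (stats::runif(1) < config$vaccination_rate) {
        out_lines <- c(out_lines, sprintf(
          "          <vaccination>%s</vaccination>",
          xml_escape(sample(FREE_TEXT$vaccination, 1))))
        n_notes_total <- n_notes_total + 1L
      }
      if (stats::runif(1) < config$supplementary_rate) {
        out_lines <- c(out_lines, sprintf(
          "          <supplementary>%s</supplementary>",
          xml_escape(sample(FREE_TEXT$supplementary, 1))))
        n_notes_total <- n_notes_total + 1L
      }
      lines <- c(lines, "        <outcome>", out_lines, "        </outcome>",
                 "      </consultation>")
    }
    lines <- c(lines, "    </consultations>")

    # laboratory result sets: one external laboratory per patient, whose
    # spelling/unit variant is fixed per analyte
    lab_idx <- sample(config$n_laboratories, 1)
    n_panels <- stats::rpois(1, config$mean_lab_panels_per_patient)
    lab_rows <- NULL
    lines <- c(lines, "    <lab-results>")
    if (n_panels > 0) {
      pdates <- sort(rdate(n_panels, registration, horizon))
      for (p in seq_len(n_panels)) {
        link <- if (n_visits > 0 && stats::runif(1) < 0.5) {
          prior <- which(visit_dates <= pdates[p])
          if (length(prior)) cons_ids[max(prior)] else NA_character_
        } else NA_character_
        k <- sample(4:min(8, length(analytes) + 2), 1)
        chosen <- sample(analytes, min(k, length(analytes)))
        lines <- c(lines, sprintf(
          "      <result-set laboratory=\"LAB%d\" date=\"%s\"%s>",
          lab_idx, fmt_date(pdates[p]),
          if (is.na(link)) "" else sprintf(" consultation-ref=\"%s\"", link)))
        for (an in chosen) {
          variants <- config$lab_vocabulary_variants[[an]]
          vi <- (lab_idx - 1L) %% nrow(variants) + 1L
          vv <- variants[vi, ]
          val <- round_half_up(max(stats::rnorm(1, vv$mean, vv$sd), 0.01), 2)
          lines <- c(lines, sprintf(
            "        <result variable=\"%s\" value=\"%s\" unit=\"%s\"/>",
            xml_escape(vv$label), sprintf("%.2f", val), xml_escape(vv$unit)))
          lab_rows <- rbind(lab_rows, data.frame(
            patient_id = pid, date = fmt_date(pdates[p]),
            consultation_ref = if (is.na(link)) NA_character_ else link,
            analyte = an, label = vv$label, unit = vv$unit, value = val,
            laboratory = sprintf("LAB%d", lab_idx)))
        }
        lines <- c(lines, "      </result-set>")
      }
    }
    lines <- c(lines, "    </lab-results>")

    # external clinical reports from specialist physicians
    n_rep <- stats::rpois(1, config$mean_clinical_reports)
    rep_rows <- NULL
    if (n_rep > 0) {
      rdates <- rdate(n_rep, registration, horizon)
      rep_rows <- data.frame(patient_id = pid, date = fmt_date(rdates))
      lines <- c(lines, "    <clinical-reports>")
      lines <- c(lines, sprintf(
        "      <report date=\"%s\">%s</report>", fmt_date(rdates),
        xml_escape(sample(FREE_TEXT$clinical_report, n_rep, replace = TRUE))))
      lines <- c(lines, "    </clinical-reports>")
      n_notes_total <- n_notes_total + n_rep
    }

    lines <- c(lines,
      "    <addresses>",
      sprintf("      <address line=\"%s\" town=\"%s\" postal-code=\"%s\" country=\"%s\"/>",
              xml_escape(addr$line), xml_escape(addr$town),
              addr$postal_code, addr$country),
      "    </addresses>",
      "  </patient>",
      "</patient-export>")

    path <- file.path(dir, paste0(pid, ".xml"))
    writeLines(lines, path, useBytes = TRUE)
    files[i] <- path

    truth_pat[[i]] <- data.frame(
      patient_id = pid, physician = phys, sex = sex, year_of_birth = yob,
      town = ifelse(is.na(town), NA_character_, town),
      registration_date = fmt_date(registration),
      death_date = ifelse(dead, fmt_date(death_date), NA_character_),
      n_consultations = n_visits)
    if (n_visits > 0)
      truth_cons[[i]] <- data.frame(consultation_id = cons_ids,
                                    patient_id = pid,
                                    date = fmt_date(visit_dates))
    truth_rx[[i]] <- rx_rows
    truth_lab[[i]] <- lab_rows
    truth_bio[[i]] <- bio_rows
    truth_hist[[i]] <- hist_rows
    truth_rep[[i]] <- rep_rows
  }

  truth <- list(
    patients = do.call(rbind, truth_pat),
    consultations = rbind_all(truth_cons,
      data.frame(consultation_id = character(0), patient_id = character(0),
                 date = character(0))),
    prescriptions = rbind_all(truth_rx,
      data.frame(patient_id = character(0), consultation_id = character(0),
                 date = character(0), cip = character(0), name = character(0),
                 atc = character(0), days_supply = integer(0),
                 refills = integer(0), quantity = integer(0))),
    lab_results = rbind_all(truth_lab,
      data.frame(patient_id = character(0), date = character(0),
                 consultation_ref = character(0), analyte = character(0),
                 label = character(0), unit = character(0),
                 value = numeric(0), laboratory = character(0))),
    biometrics = rbind_all(truth_bio,
      data.frame(patient_id = character(0), consultation_id = character(0),
                 date = character(0), variable = character(0),
                 value = numeric(0), unit = character(0))),
    histories = rbind_all(truth_hist,
      data.frame(patient_id = character(0), coded = logical(0),
                 icd10 = character(0), date = character(0))),
    clinical_reports = rbind_all(truth_rep,
      data.frame(patient_id = character(0), date = character(0)))
  )

  manifest <- build_manifest(truth, n_notes_total, config)
  export <- structure(
    list(dir = dir, files = files, schema_version = EXPORT_SCHEMA_VERSION),
    class = "source_export")
  write_manifest(manifest, file.path(dir, "manifest.json"))
  list(export = export, manifest = manifest)
}

# Recompute the derived manifest blocks (counts, per-physician counts,
# per-patient event-date extents) from the truth tables, so defect injection
# can update the truth and re-derive consistently.
build_manifest <- function(truth, n_notes_total, config,
                           injected_defects = NULL) {
  pats <- truth$patients
  ext <- lapply(seq_len(nrow(pats)), function(i) {
    pid <- pats$patient_id[i]
    dates <- c(pats$registration_date[i],
               truth$consultations$date[truth$consultations$patient_id == pid],
               truth$lab_results$date[truth$lab_results$patient_id == pid],
               truth$histories$date[truth$histories$patient_id == pid],
               truth$clinical_reports$date[
                 truth$clinical_reports$patient_id == pid])
    dates <- dates[!is.na(dates)]
    data.frame(patient_id = pid,
               first_event_date = min(dates), last_event_date = max(dates))
  })
  per_phys <- table(pats$physician)
  manifest <- list(
    schema_version = EXPORT_SCHEMA_VERSION,
    seed = config$seed,
    counts = list(
      true_n_patients = nrow(pats),
      true_n_consultations = nrow(truth$consultations),
      true_n_prescriptions = nrow(truth$prescriptions),
      true_n_lab_results = nrow(truth$lab_results),
      true_n_biometrics = nrow(truth$biometrics),
      true_n_deaths = sum(!is.na(pats$death_date)),
      true_n_note_items = n_notes_total,
      true_n_histories = nrow(truth$histories),
      true_n_histories_coded = sum(truth$histories$coded),
      true_n_addresses = nrow(pats)
    ),
    per_physician_patient_counts = as.list(per_phys),
    per_patient_event_date_extents = do.call(rbind, ext),
    truth = truth,
    injected_defects = injected_defects %||% data.frame(
      kind = character(0), patient_ref = character(0), detail = character(0))
  )
  class(manifest) <- "ground_truth_manifest"
  manifest
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @export
print.ground_truth_manifest <- function(x, ...) {
  cat("<ground_truth_manifest>\n")
  for (nm in names(x$counts)) cat(sprintf("  %s: %d\n", nm, x$counts[[nm]]))
  cat(sprintf("  injected defects: %d\n", nrow(x$injected_defects)))
  invisible(x)
}

#' @export
print.source_export <- function(x, ...) {
  cat(sprintf("<source_export: %d patient documents in %s (schema %s)>\n",
              length(x$files), x$dir, x$schema_version))
  invisible(x)
}

# -- defect injection -------------------------------------------------------

DEFECT_KINDS <- c("event_after_death", "value_out_of_range",
                  "birth_year_implausible", "dangling_visit_reference",
                  "missing_required_field")

#' Inject known data defects into a synthetic export
#'
#' Applies a requested number of defects of each kind to the on-disk export
#' and returns an updated manifest whose `injected_defects` table locates
#' each one. With an empty spec the export is untouched byte-for-byte.
#' Defect kinds: `event_after_death` (a consultation is re-dated after the
#' patient's death), `value_out_of_range` (a potassium result is scaled x100),
#' `birth_year_implausible` (year of birth set to 1850),
#' `dangling_visit_reference` (a laboratory result set points to a
#' non-existent consultation), `missing_required_field` (the sex attribute is
#' removed).
#'
#' @param export a `source_export` from [generate_export()].
#' @param manifest the matching `ground_truth_manifest`.
#' @param spec named integer vector/list, e.g. `c(event_after_death = 3)`.
#' @param seed RNG seed for candidate selection.
#' @return list with updated `export` and `manifest`.
#' @export
inject_defects <- function(export, manifest, spec = list(), seed = 1L) {
  spec <- unlist(spec)
  if (length(spec) == 0)
    return(list(export = export, manifest = manifest))
  bad <- setdiff(names(spec), DEFECT_KINDS)
  if (length(bad))
    etl_stop("config", "unknown defect kind(s): %s", paste(bad, collapse = ", "))
  set.seed(seed)
  truth <- manifest$truth
  defects <- manifest$injected_defects

  edit_doc <- function(pid, fn) {
    path <- file.path(export$dir, paste0(pid, ".xml"))
    doc <- xml2::read_xml(path)
    fn(doc)
    xml2::write_xml(doc, path)
  }

  for (kind in names(spec)) {
    n <- as.integer(spec[[kind]])
    if (n == 0) next
    if (kind == "event_after_death") {
      cand <- truth$patients$patient_id[
        !is.na(truth$patients$death_date) &
          truth$patients$patient_id %in% truth$consultations$patient_id]
      if (length(cand) < n)
        etl_stop("capacity",
                 "requested %d event_after_death defects but only %d deceased patients with consultations",
                 n, length(cand))
      for (pid in sample_vec(cand, n)) {
        dd <- as_iso_date(truth$patients$death_date[
          truth$patients$patient_id == pid])
        rows <- which(truth$consultations$patient_id == pid)
        row <- rows[length(rows)]
        cid <- truth$consultations$consultation_id[row]
        new_date <- fmt_date(dd + sample(1:30, 1))
        edit_doc(pid, function(doc) {
          node <- xml2::xml_find_first(
            doc, sprintf("//consultation[@id='%s']", cid))
          xml2::xml_set_attr(node, "date", new_date)
        })
        truth$consultations$date[row] <- new_date
        sel <- truth$prescriptions$consultation_id == cid
        truth$prescriptions$date[sel] <- new_date
        sel <- truth$biometrics$consultation_id == cid
        truth$biometrics$date[sel] <- new_date
        defects <- rbind(defects, data.frame(
          kind = kind, patient_ref = pid,
          detail = sprintf("consultation %s re-dated %s (death %s)",
                           cid, new_date, fmt_date(dd))))
      }
    } else if (kind == "value_out_of_range") {
      cand <- which(truth$lab_results$analyte == "potassium")
      if (length(cand) < n)
        etl_stop("capacity",
                 "requested %d value_out_of_range defects but only %d potassium results",
                 n, length(cand))
      for (row in sample_vec(cand, n)) {
        r <- truth$lab_results[row, ]
        new_val <- sprintf("%.2f", r$value * 100)
        edit_doc(r$patient_id, function(doc) {
          node <- xml2::xml_find_first(doc, sprintf(
            "//result-set[@date='%s']/result[@variable='%s' and @value='%s']",
            r$date, r$label, sprintf("%.2f", r$value)))
          xml2::xml_set_attr(node, "value", new_val)
        })
        truth$lab_results$value[row] <- r$value * 100
        defects <- rbind(defects, data.frame(
          kind = kind, patient_ref = r$patient_id,
          detail = sprintf("potassium result on %s set to %s %s",
                           r$date, new_val, r$unit)))
      }
    } else if (kind == "birth_year_implausible") {
      cand <- truth$patients$patient_id
      if (length(cand) < n)
        etl_stop("capacity", "requested %d birth_year defects for %d patients",
                 n, length(cand))
      for (pid in sample_vec(cand, n)) {
        edit_doc(pid, function(doc) {
          node <- xml2::xml_find_first(doc, "//demographics")
          xml2::xml_set_attr(node, "year-of-birth", "1850")
        })
        truth$patients$year_of_birth[truth$patients$patient_id == pid] <- 1850L
        defects <- rbind(defects, data.frame(
          kind = kind, patient_ref = pid, detail = "year of birth set to 1850"))
      }
    } else if (kind == "dangling_visit_reference") {
      cand <- unique(truth$lab_results[, c("patient_id", "date")])
      if (nrow(cand) < n)
        etl_stop("capacity",
                 "requested %d dangling_visit_reference defects but only %d result sets",
                 n, nrow(cand))
      pick <- cand[sample_vec(seq_len(nrow(cand)), n), , drop = FALSE]
      for (row in seq_len(nrow(pick))) {
        pid <- pick$patient_id[row]; pdate <- pick$date[row]
        ghost <- sprintf("%s-cGHOST%02d", pid, row)
        edit_doc(pid, function(doc) {
          node <- xml2::xml_find_first(doc, sprintf(
            "//result-set[@date='%s']", pdate))
          xml2::xml_set_attr(node, "consultation-ref", ghost)
        })
        sel <- truth$lab_results$patient_id == pid & truth$lab_results$date == pdate
        truth$lab_results$consultation_ref[sel] <- ghost
        defects <- rbind(defects, data.frame(
          kind = kind, patient_ref = pid,
          detail = sprintf("result set on %s references missing consultation %s",
                           pdate, ghost)))
      }
    } else if (kind == "missing_required_field") {
      cand <- truth$patients$patient_id[!is.na(truth$patients$sex)]
      if (length(cand) < n)
        etl_stop("capacity", "requested %d missing_required_field defects, %d candidates",
                 n, length(cand))
      for (pid in sample_vec(cand, n)) {
        edit_doc(pid, function(doc) {
          node <- xml2::xml_find_first(doc, "//demographics")
          xml2::xml_set_attr(node, "sex", NULL)
        })
        truth$patients$sex[truth$patients$patient_id == pid] <- NA_character_
        defects <- rbind(defects, data.frame(
          kind = kind, patient_ref = pid,
          detail = "sex attribute removed from demographics"))
      }
    }
  }

  new_manifest <- build_manifest(truth, manifest$counts$true_n_note_items,
                                 list(seed = manifest$seed),
                                 injected_defects = defects)
  write_manifest(new_manifest, file.path(export$dir, "manifest.json"))
  list(export = export, manifest = new_manifest)
}

# sample() misbehaves on length-1 numeric vectors; defect injection selects
# from candidate vectors that may have length 1
sample_vec <- function(x, n) x[sample.int(length(x), n)]
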