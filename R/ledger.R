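# Mapping ledger: one row per distinct source vocabulary item, carrying its
# normalized label, difficulty level, the two annotators' candidate concepts,
# the consensus standard concept, and the number of staging records the item
# covers. The ledger is the hand-off between semantic mapping and the
# structural transform.

ledger_template <- function() {
  data.frame(
    item_id = character(0), feature = character(0),
    raw_label = character(0), normalized_label = character(0),
    source_vocabulary = character(0), source_code = character(0),
    unit = character(0), difficulty_level = integer(0),
    local_concept_id = numeric(0),
    annotator_A = numeric(0), annotator_B = numeric(0),
    consensus_concept_id = numeric(0), adjudicated = logical(0),
    pending = logical(0), n_records = integer(0))
}

#' Build a mapping ledger from a staging store
#'
#' Enumerates every distinct source vocabulary item (sex values, biometric
#' variables, laboratory variables, units, ICD-10 history codes, CIP drug
#' codes, and the free-text note classes), normalizes labels, classifies the
#' mapping difficulty against the concept store, and registers one local
#' concept (id > 2,000,000,000) per structured item so its source concept can
#' travel into the warehouse.
#'
#' @param staging a `staging_store`.
#' @param store a `concept_store` (mutated: local concepts are registered).
#' @param abbreviations,stopwords passed to [normalize_label()].
#' @return a `mapping_ledger` data.frame.
#' @export
build_ledger <- function(staging, store,
                         abbreviations = default_abbreviations(),
                         stopwords = default_stopwords()) {
  items <- list()
  add <- function(feature, raw_label, vocab, code = NA_character_,
                  unit = NA_character_, structured = TRUE, n_records,
                  domain) {
    raw <- ifelse(is.na(raw_label), "", raw_label)
    code <- rep_len(as.character(code), length(raw))
    unit <- rep_len(as.character(unit), length(raw))
    norm <- if (structured) normalize_label(raw, abbreviations, stopwords)
            else raw
    lvl <- vapply(seq_along(raw), function(i)
      classify_difficulty(list(label = raw[i], code = code[i],
                               vocabulary = vocab, structured = structured),
                          store), integer(1))
    local_id <- rep(NA_real_, length(raw))
    if (structured) {
      for (i in seq_along(raw)) {
        lbl <- if (nzchar(norm[i])) norm[i] else raw[i]
        if (!nzchar(lbl)) lbl <- paste0("unlabelled ", feature, " item")
        local_id[i] <- register_local_concept(
          store, lbl, paste0("Weda-", feature), domain)$concept_id
      }
    }
    items[[length(items) + 1L]] <<- data.frame(
      item_id = paste0(feature, ":", ifelse(is.na(code), raw, code),
                       ifelse(is.na(unit), "", paste0("|", unit))),
      feature = feature, raw_label = raw, normalized_label = norm,
      source_vocabulary = vocab, source_code = code,
      unit = unit, difficulty_level = lvl, local_concept_id = local_id,
      annotator_A = NA_real_, annotator_B = NA_real_,
      consensus_concept_id = NA_real_, adjudicated = FALSE, pending = FALSE,
      n_records = n_records)
  }

  # sex values
  sx <- table(staging$patients$sex[!is.na(staging$patients$sex)])
  if (length(sx))
    add("sex", names(sx), "Weda-patient", n_records = as.integer(sx),
        domain = "Observation")

  # biometric variables (label only; the unit is its own feature)
  if (nrow(staging$biometrics)) {
    bio <- stats::aggregate(
      list(n = staging$biometrics$patient_id),
      by = list(raw = staging$biometrics$variable), FUN = length)
    add("biometric", bio$raw, "Weda-biometric", n_records = bio$n,
        domain = "Measurement")
  }

  # laboratory variables: distinct (label, unit) pairs as reported by each
  # laboratory
  if (nrow(staging$lab_results)) {
    lab <- stats::aggregate(
      list(n = staging$lab_results$patient_id),
      by = list(raw = staging$lab_results$variable,
                unit = staging$lab_results$unit), FUN = length)
    add("laboratory", lab$raw, "Weda-lab", unit = lab$unit,
        n_records = lab$n, domain = "Measurement")
  }

  # measurement units
  units <- table(c(staging$biometrics$unit, staging$lab_results$unit))
  if (length(units))
    add("unit", names(units), "Weda-unit", n_records = as.integer(units),
        domain = "Unit")

  # ICD-10-coded medical histories
  coded <- staging$histories[staging$histories$coded, , drop = FALSE]
  if (nrow(coded)) {
    icd <- table(coded$icd10)
    add("history_icd10", names(icd), "ICD10", code = names(icd),
        n_records = as.integer(icd), domain = "Condition")
  }

  # CIP-coded drug prescriptions
  if (nrow(staging$prescriptions)) {
    cip <- table(staging$prescriptions$cip)
    add("drug", names(cip), "CIP", code = names(cip),
        n_records = as.integer(cip), domain = "Drug")
  }

  # free-text features (level 4, out of mapping scope)
  if (nrow(staging$notes)) {
    cls <- table(staging$notes$class)
    add("free_text", names(cls), "Weda-text", structured = FALSE,
        n_records = as.integer(cls), domain = "Observation")
  }

  ledger <- rbind_all(items, ledger_template())
  class(ledger) <- c("mapping_ledger", "data.frame")
  ledger
}

#' Record the two annotators' choices and the consensus for a ledger item
#'
#' Agreement fixes the consensus at the common choice; a disagreement is
#' settled by the adjudicator (third expert) and flagged `adjudicated`; a
#' disagreement without an adjudicator leaves the item `pending` (not an
#' error). When a consensus is reached and the item carries a local concept,
#' a "Maps to" relationship to the standard concept is appended to the store.
#'
#' @param ledger a `mapping_ledger`.
#' @param item_id the item's identifier.
#' @param annotator_A,annotator_B candidate standard concept_ids (both must
#'   be present).
#' @param adjudicator optional concept_id settling a disagreement.
#' @param store optional `concept_store` to receive the "Maps to" link.
#' @return the updated ledger.
#' @export
record_consensus <- function(ledger, item_id, annotator_A, annotator_B,
                             adjudicator = NULL, store = NULL) {
  row <- which(ledger$item_id == item_id)
  if (length(row) != 1)
    etl_stop("input", "ledger item '%s' not found", item_id)
  if (is.null(annotator_A) || is.null(annotator_B) ||
      is.na(annotator_A) || is.na(annotator_B))
    etl_stop("input", "both annotations must be present for item '%s'",
             item_id)
  if (ledger$difficulty_level[row] == 4L)
    etl_stop("input", "item '%s' is free text (level 4): out of mapping scope",
             item_id)
  ledger$annotator_A[row] <- annotator_A
  ledger$annotator_B[row] <- annotator_B
  if (annotator_A == annotator_B) {
    ledger$consensus_concept_id[row] <- annotator_A
    ledger$adjudicated[row] <- FALSE
    ledger$pending[row] <- FALSE
  } else if (!is.null(adjudicator) && !is.na(adjudicator)) {
    ledger$consensus_concept_id[row] <- adjudicator
    ledger$adjudicated[row] <- TRUE
    ledger$pending[row] <- FALSE
  } else {
    ledger$pending[row] <- TRUE
    return(ledger)
  }
  if (!is.null(store) && !is.na(ledger$local_concept_id[row]))
    add_relationship(store, ledger$local_concept_id[row],
                     ledger$consensus_concept_id[row], "Maps to")
  ledger
}

# -- deterministic annotation emulation -------------------------------------

# Target standard vocabulary per structured feature.
FEATURE_TARGETS <- c(sex = "Gender", biometric = "SNOMED",
                     laboratory = "LOINC", unit = "UCUM",
                     history_icd10 = "ICD10", drug = "RxNorm")

#' Annotate a ledger deterministically against the concept store
#'
#' Emulates the dual-annotation protocol without humans so the pipeline is
#' reproducible end to end: annotator A matches the normalized label exactly
#' (order-insensitive on tokens) against normalized standard concept names of
#' the feature's target vocabulary; annotator B takes the best fuzzy
#' suggestion at the given similarity threshold; disagreements are settled in
#' favour of the exact match. Level-1 items (codes already standard) take the
#' standard concept directly; drug items run the two-hop CIP mapping; level-4
#' items are left unmapped. Units are matched on the UCUM concept code.
#'
#' @param ledger a `mapping_ledger` from [build_ledger()].
#' @param store a `concept_store` (mutated: "Maps to" links are appended).
#' @param min_similarity fuzzy threshold for annotator B.
#' @return the annotated ledger.
#' @export
annotate_ledger <- function(ledger, store, min_similarity = 0.85) {
  std <- store$concept[store$concept$standard_concept == "S", , drop = FALSE]
  std_key <- label_match_key(normalize_label(std$concept_name))
  for (row in seq_len(nrow(ledger))) {
    lvl <- ledger$difficulty_level[row]
    feature <- ledger$feature[row]
    if (lvl == 4L) next
    if (lvl == 1L) {
      hit <- concept_by_code(store, ledger$source_vocabulary[row],
                             ledger$source_code[row])
      ledger$consensus_concept_id[row] <- hit$concept_id[1]
      next
    }
    if (feature == "drug") {
      m <- map_drug(ledger$source_code[row], store)
      if (m$status == "mapped") {
        ledger <- record_consensus(ledger, ledger$item_id[row],
                                   m$rxnorm_concept_id, m$rxnorm_concept_id,
                                   store = store)
      }
      next
    }
    target <- FEATURE_TARGETS[[feature]] %||% NA_character_
    if (is.na(target)) next
    cand <- which(std$vocabulary_id == target)
    if (!length(cand)) next
    a <- NA_real_
    if (feature == "unit") {
      hit <- cand[tolower(std$concept_code[cand]) ==
                    tolower(ledger$raw_label[row])]
      if (length(hit)) a <- std$concept_id[hit[1]]
    } else {
      key <- label_match_key(ledger$normalized_label[row])
      hit <- cand[std_key[cand] == key]
      if (length(hit)) a <- std$concept_id[hit[1]]
    }
    sug <- suggest_concepts(ledger$raw_label[row], store, target,
                            min_similarity = min_similarity, n = 1)
    b <- if (nrow(sug)) sug$concept_id[1] else NA_real_
    if (feature == "unit" && is.na(b)) b <- a
    if (is.na(a) && is.na(b)) next          # stays unmapped (concept 0 later)
    if (is.na(a)) a <- b
    if (is.na(b)) b <- a
    ledger <- record_consensus(ledger, ledger$item_id[row], a, b,
                               adjudicator = a, store = store)
  }
  ledger
}

# consensus lookup helpers used by the structural transform ------------------

ledger_lookup <- function(ledger, feature, raw, unit = NULL) {
  sel <- ledger$feature == feature & ledger$raw_label == raw
  if (!is.null(unit)) sel <- sel & (is.na(ledger$unit) | ledger$unit == unit)
  row <- which(sel)
  if (!length(row)) return(list(concept = 0, source_concept = 0))
  list(concept = ledger$consensus_concept_id[row[1]] %|NA|% 0,
       source_concept = ledger$local_concept_id[row[1]] %|NA|% 0)
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

# -- coverage report --------------------------------------------------------

#' Concept-mapping coverage report
#'
#' One row per (feature, source vocabulary): number of distinct concepts,
#' mapped concepts n/N with a percentage, and mapped records n/N with a
#' percentage. Percentages are rounded to one decimal, half away from zero.
#' Level-4 (free text) rows carry no mapping fractions.
#'
#' @param ledger an annotated `mapping_ledger`.
#' @return a `coverage_report` data.frame.
#' @export
coverage_report <- function(ledger) {
  keys <- unique(ledger[, c("feature", "source_vocabulary",
                            "difficulty_level")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- ledger$feature == keys$feature[i] &
      ledger$source_vocabulary == keys$source_vocabulary[i]
    sub <- ledger[sel, , drop = FALSE]
    lvl <- keys$difficulty_level[i]
    n_concepts <- nrow(sub)
    if (lvl == 4L) {
      data.frame(feature = keys$feature[i],
                 source_vocabulary = keys$source_vocabulary[i],
                 target_vocabulary = NA_character_,
                 difficulty_level = lvl, n_concepts = n_concepts,
                 mapped_concepts_n = NA_integer_,
                 mapped_concepts_N = NA_integer_,
                 mapped_concepts_pct = NA_real_,
                 mapped_records_n = NA_integer_,
                 mapped_records_N = NA_integer_,
                 mapped_records_pct = NA_real_)
    } else {
      mapped <- !is.na(sub$consensus_concept_id)
      n <- sum(mapped); N <- n_concepts
      rn <- sum(sub$n_records[mapped]); rN <- sum(sub$n_records)
      data.frame(feature = keys$feature[i],
                 source_vocabulary = keys$source_vocabulary[i],
                 target_vocabulary = FEATURE_TARGETS[[keys$feature[i]]] %||%
                   NA_character_,
                 difficulty_level = lvl, n_concepts = n_concepts,
                 mapped_concepts_n = n, mapped_concepts_N = N,
                 mapped_concepts_pct = coverage_percent(n, N),
                 mapped_records_n = rn, mapped_records_N = rN,
                 mapped_records_pct = coverage_percent(rn, rN))
    }
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(rep$difficulty_level, rep$feature), ]
  rownames(rep) <- NULL
  class(rep) <- c("coverage_report", "data.frame")
  rep
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Concept mapping coverage\n")
  for (i in seq_len(nrow(x))) {
    if (is.na(x$mapped_concepts_pct[i])) {
      cat(sprintf("  %-14s level %d  free text (unmapped)\n",
                  x$feature[i], x$difficulty_level[i]))
    } else {
      cat(sprintf(
        "  %-14s level %d  concepts %d/%d (%.1f%%)  records %d/%d (%.1f%%)\n",
        x$feature[i], x$difficulty_level[i],
        x$mapped_concepts_n[i], x$mapped_concepts_N[i],
        x$mapped_concepts_pct[i],
        x$mapped_records_n[i], x$mapped_records_N[i],
        x$mapped_records_pct[i]))
    }
  }
  invisible(x)
}
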