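# Concept store and semantic mapping: standard + local vocabularies, the
# four-level mapping difficulty classification, label normalization, two-hop
# CIP -> ATC -> RxNorm drug mapping, dual-annotator reconciliation with
# Cohen's kappa, local-concept registration (ids > 2,000,000,000) and the
# coverage report.

LOCAL_ID_FLOOR <- 2000000000

# -- concept store ----------------------------------------------------------

new_concept_store <- function(concept, relationship, vocabulary) {
  env <- new.env(parent = emptyenv())
  env$concept <- concept
  env$concept_relationship <- relationship
  env$vocabulary <- vocabulary
  env$next_local_id <- LOCAL_ID_FLOOR + 1
  class(env) <- "concept_store"
  env
}

#' Load a vocabulary fixture into a concept store
#'
#' Reads CONCEPT, CONCEPT_RELATIONSHIP and VOCABULARY tables (CSV with OMOP
#' column names) and validates uniqueness and referential integrity before
#' accepting them. Relationship rows whose endpoints are missing from the
#' CONCEPT table are an integrity error listing the offenders.
#'
#' @param dir directory containing `CONCEPT.csv`, `CONCEPT_RELATIONSHIP.csv`
#'   and `VOCABULARY.csv`. Defaults to the fixture bundled with the package
#'   (a synthetic ~200-concept stand-in for an OHDSI vocabulary download).
#' @return a `concept_store`.
#' @export
load_vocabulary_fixture <- function(dir = system.file("extdata", "vocab",
                                                      package = "omopetl")) {
  read1 <- function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path))
      etl_stop("input", "vocabulary fixture is missing %s.csv in '%s'",
               name, dir)
    utils::read.csv(path, colClasses = "character")
  }
  concept <- read1("CONCEPT")
  rel <- read1("CONCEPT_RELATIONSHIP")
  vocab <- read1("VOCABULARY")
  concept$concept_id <- as.numeric(concept$concept_id)
  rel$concept_id_1 <- as.numeric(rel$concept_id_1)
  rel$concept_id_2 <- as.numeric(rel$concept_id_2)
  validate_concept_tables(concept, rel, vocab)
  new_concept_store(concept, rel, vocab)
}

validate_concept_tables <- function(concept, rel, vocab) {
  need <- c("concept_id", "concept_name", "domain_id", "vocabulary_id",
            "concept_code", "standard_concept")
  if (!all(need %in% names(concept)))
    etl_stop("input", "CONCEPT is missing columns: %s",
             paste(setdiff(need, names(concept)), collapse = ", "))
  dup <- concept$concept_id[duplicated(concept$concept_id)]
  if (length(dup))
    etl_stop("integrity", "duplicate concept_id(s): %s",
             paste(unique(dup), collapse = ", "))
  dangling <- unique(c(setdiff(rel$concept_id_1, concept$concept_id),
                       setdiff(rel$concept_id_2, concept$concept_id)))
  if (length(dangling))
    etl_stop("integrity",
             "relationship endpoints missing from CONCEPT: %s",
             paste(dangling, collapse = ", "))
  missing_vocab <- setdiff(unique(concept$vocabulary_id),
                           vocab$vocabulary_id)
  if (length(missing_vocab))
    etl_stop("integrity", "vocabulary_id(s) not declared in VOCABULARY: %s",
             paste(missing_vocab, collapse = ", "))
  # "Maps to" must land on a standard concept
  mt <- rel[rel$relationship_id == "Maps to", ]
  if (nrow(mt)) {
    std <- concept$concept_id[concept$standard_concept == "S"]
    bad <- setdiff(mt$concept_id_2, std)
    if (length(bad))
      etl_stop("integrity", "'Maps to' targets non-standard concept(s): %s",
               paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.concept_store <- function(x, ...) {
  n_local <- sum(x$concept$concept_id > LOCAL_ID_FLOOR)
  cat(sprintf(
    "<concept_store: %d concepts (%d local), %d relationships, %d vocabularies>\n",
    nrow(x$concept), n_local, nrow(x$concept_relationship),
    nrow(x$vocabulary)))
  invisible(x)
}

store_concept <- function(store, id) {
  store$concept[match(id, store$concept$concept_id), , drop = FALSE]
}

concept_by_code <- function(store, vocabulary, code) {
  store$concept[store$concept$vocabulary_id == vocabulary &
                  store$concept$concept_code == code, , drop = FALSE]
}

rel_targets <- function(store, id, relationship) {
  r <- store$concept_relationship
  r$concept_id_2[r$concept_id_1 %in% id & r$relationship_id == relationship]
}

#' Register a local concept
#'
#' Allocates a new concept identifier strictly greater than 2,000,000,000
#' from a monotonic sequence. Re-registering an identical (label, vocabulary,
#' domain) triple returns the existing concept; no duplicates are created.
#'
#' @param store a `concept_store`.
#' @param label concept name (normalized label); must be non-empty.
#' @param vocabulary local vocabulary identifier (added to VOCABULARY if new).
#' @param domain OMOP domain (`Condition`, `Measurement`, `Drug`, `Unit`,
#'   `Observation`, `Visit`, `Type`).
#' @return one-row data.frame: the registered concept.
#' @export
register_local_concept <- function(store, label, vocabulary, domain) {
  if (is.na(label) || !nzchar(label))
    etl_stop("input", "cannot register a local concept with an empty label")
  existing <- store$concept[
    store$concept$concept_name == label &
      store$concept$vocabulary_id == vocabulary &
      store$concept$domain_id == domain, , drop = FALSE]
  if (nrow(existing)) return(existing[1, , drop = FALSE])
  id <- store$next_local_id
  store$next_local_id <- store$next_local_id + 1
  row <- data.frame(concept_id = id, concept_name = label,
                    domain_id = domain, vocabulary_id = vocabulary,
                    concept_code = paste0("local-", id),
                    standard_concept = "")
  store$concept <- rbind(store$concept[, names(row)], row)
  if (!vocabulary %in% store$vocabulary$vocabulary_id)
    store$vocabulary <- rbind(store$vocabulary, data.frame(
      vocabulary_id = vocabulary,
      vocabulary_name = paste("Local vocabulary:", vocabulary)))
  row
}

add_relationship <- function(store, id1, id2, relationship) {
  if (relationship == "Maps to") {
    tgt <- store_concept(store, id2)
    if (!nrow(tgt) || is.na(tgt$standard_concept) ||
        tgt$standard_concept != "S")
      etl_stop("integrity",
               "'Maps to' target %s is not a standard concept", id2)
  }
  exists <- any(store$concept_relationship$concept_id_1 == id1 &
                  store$concept_relationship$concept_id_2 == id2 &
                  store$concept_relationship$relationship_id == relationship)
  if (!exists)
    store$concept_relationship <- rbind(
      store$concept_relationship,
      data.frame(concept_id_1 = id1, concept_id_2 = id2,
                 relationship_id = relationship))
  invisible(store)
}

# -- label normalization ----------------------------------------------------

#' Default stop words for label normalization
#'
#' French/English filler words plus unit tokens; unit tokens are dropped from
#' labels because units travel in their own field in the source export.
#' @return character vector.
#' @export
default_stopwords <- function() {
  c("of", "to", "an", "a", "the", "in", "de", "du", "des", "la", "le",
    "les", "en", "dans", "et", "pour", "par", "sur",
    "serum", "serique", "sanguin", "sang", "plasma", "taux", "dosage",
    "mmol", "umol", "mol", "mg", "g", "dl", "l", "ml", "kg", "cm",
    "mmhg", "min", "ui", "u")
}

#' Default abbreviation dictionary for label normalization
#'
#' Maps laboratory and biometric shorthand (including multi-token French
#' labels) to the full analyte or measure name, e.g. "CRP" to
#' "C-reactive protein". Keys are matched case-insensitively on whole token
#' sequences, longest key first.
#' @return named character vector (abbreviation -> expansion).
#' @export
default_abbreviations <- function() {
  c("crp" = "C-reactive protein",
    "m" = "male",
    "f" = "female",
    "k" = "potassium",
    "na" = "sodium",
    "hb" = "hemoglobin",
    "hemoglobine" = "hemoglobin",
    "create" = "creatinine",
    "glycemie" = "glucose",
    "ta systolique" = "systolic blood pressure",
    "ta diastolique" = "diastolic blood pressure",
    "frequence cardiaque" = "heart rate",
    "pouls" = "heart rate",
    "poids" = "body weight",
    "taille" = "body height",
    "imc" = "body mass index")
}

#' Normalize a raw vocabulary label
#'
#' Applies, in order: strip leading chapter/line numbers; remove punctuation
#' and special characters (intra-word hyphens are kept so expanded names like
#' "c-reactive protein" survive); expand abbreviations (whole-token,
#' case-insensitive, longest key first); case-fold; remove stop words;
#' collapse whitespace. The function is idempotent:
#' `normalize_label(normalize_label(x))` equals `normalize_label(x)`.
#'
#' @param raw character vector of raw labels (non-null).
#' @param abbreviations named character vector, see
#'   [default_abbreviations()].
#' @param stopwords character vector, see [default_stopwords()].
#' @return character vector of canonical labels; empty strings are allowed
#'   (flagged by the caller, not an error).
#' @export
#' @examples
#' normalize_label("CRP")                      # "c-reactive protein"
#' normalize_label("3. Potassium (mmol/L):",
#'                 abbreviations = character(0),
#'                 stopwords = c("of", "to", "an"))  # "potassium mmol l"
normalize_label <- function(raw, abbreviations = default_abbreviations(),
                            stopwords = default_stopwords()) {
  if (any(is.na(raw))) etl_stop("input", "normalize_label: raw label is NA")
  strip_leading_numbers <- function(x) {
    # stripped to a fixed point; bare digits glued to a word ("5b") are not
    # chapter numbers
    repeat {
      x2 <- sub("^\\s*\\d+\\s*[.)-]\\s*|^\\s*\\d+\\s+", "", x)
      if (identical(x2, x)) return(x)
      x <- x2
    }
  }
  vapply(raw, function(x) {
    # 1. leading chapter/line numbers ("3.", "12)", "4 -")
    x <- strip_leading_numbers(x)
    # 2. punctuation/special characters -> space, keep intra-word hyphens;
    # re-strip numbers the punctuation removal may have exposed (keeps the
    # whole pipeline idempotent)
    x <- gsub("[^[:alnum:][:space:]-]", " ", x)
    x <- gsub("(^|[[:space:]])-+", "\\1 ", x)
    x <- gsub("-+([[:space:]]|$)", " \\1", x)
    x <- strip_leading_numbers(x)
    # 3. abbreviation expansion on token sequences, longest key first
    tokens <- strsplit(trimws(gsub("[[:space:]]+", " ", x)), " ")[[1]]
    if (length(abbreviations) && length(tokens)) {
      keys <- strsplit(tolower(names(abbreviations)), " ")
      ord <- order(lengths(keys), decreasing = TRUE)
      out <- character(0); i <- 1
      while (i <= length(tokens)) {
        matched <- FALSE
        for (j in ord) {
          kl <- length(keys[[j]])
          if (i + kl - 1 <= length(tokens) &&
              identical(tolower(tokens[i:(i + kl - 1)]), keys[[j]])) {
            out <- c(out, strsplit(abbreviations[[j]], " ")[[1]])
            i <- i + kl; matched <- TRUE; break
          }
        }
        if (!matched) { out <- c(out, tokens[i]); i <- i + 1 }
      }
      tokens <- out
    }
    # 4. case-fold; 5. stop words; 6. collapse whitespace
    tokens <- tolower(tokens)
    tokens <- tokens[!tokens %in% tolower(stopwords) & nzchar(tokens)]
    while (length(tokens) && grepl("^\\d+$", tokens[1]))
      tokens <- tokens[-1]
    paste(tokens, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# order-insensitive comparison key used by the deterministic annotators
label_match_key <- function(normalized) {
  vapply(strsplit(normalized, " "),
         function(t) paste(sort(t), collapse = " "), character(1))
}

#' Rank fuzzy concept suggestions for a label
#'
#' Optional helper proposing candidate standard concepts by normalized edit
#' similarity (1 - Levenshtein distance / longer length) against normalized
#' concept names. It proposes, never auto-accepts: level-3 items still
#' require annotation.
#'
#' @param label raw label.
#' @param store a `concept_store`.
#' @param vocabulary restrict candidates to this vocabulary (optional).
#' @param min_similarity similarity threshold in (0, 1]; default 0.85.
#' @param n maximum number of suggestions.
#' @return data.frame of candidate concepts with a `similarity` column,
#'   best first (possibly 0 rows).
#' @export
suggest_concepts <- function(label, store, vocabulary = NULL,
                             min_similarity = 0.85, n = 5) {
  cand <- store$concept[store$concept$standard_concept == "S", , drop = FALSE]
  if (!is.null(vocabulary))
    cand <- cand[cand$vocabulary_id %in% vocabulary, , drop = FALSE]
  if (!nrow(cand)) return(cbind(cand, similarity = numeric(0)))
  q <- normalize_label(label)
  names_n <- normalize_label(cand$concept_name)
  d <- as.vector(utils::adist(q, names_n))
  sim <- 1 - d / pmax(nchar(q), nchar(names_n), 1)
  keep <- sim >= min_similarity
  out <- cbind(cand[keep, , drop = FALSE], similarity = sim[keep])
  out <- out[order(-out$similarity), , drop = FALSE]
  utils::head(out, n)
}

# -- difficulty classification ----------------------------------------------

#' Classify the mapping difficulty of a source vocabulary item
#'
#' Level 1: the item's code is itself a standard concept in the store.
#' Level 2: the code exists as a non-standard concept with a pre-existing
#' mapping ("Maps to" or "ATC to RxNorm") to the standard vocabulary.
#' Level 3: structured but unmapped (manual annotation needed).
#' Level 4: free text (out of mapping scope).
#'
#' @param item list with elements `label`, optional `code` and `vocabulary`,
#'   and logical `structured` (default TRUE).
#' @param store a `concept_store`.
#' @return integer 1, 2, 3 or 4.
#' @export
classify_difficulty <- function(item, store) {
  if (!isTRUE(item$structured %||% TRUE)) return(4L)
  code <- item$code %||% NA_character_
  vocab <- item$vocabulary %||% NA_character_
  if (!is.na(code) && !is.na(vocab)) {
    hit <- concept_by_code(store, vocab, code)
    if (nrow(hit)) {
      if (hit$standard_concept[1] == "S") return(1L)
      mapped <- c(rel_targets(store, hit$concept_id[1], "Maps to"),
                  rel_targets(store, hit$concept_id[1], "ATC to RxNorm"))
      if (length(mapped)) return(2L)
    }
  }
  3L
}

# -- two-hop drug mapping ---------------------------------------------------

#' Map a CIP drug code to its RxNorm standard concept via ATC
#'
#' Two-hop traversal: CIP -> ATC ("CIP to ATC"), then ATC -> RxNorm
#' ("ATC to RxNorm"). The result records both hops; the code is unmapped if
#' either hop is missing.
#'
#' @param cip_code CIP presentation code (7 or 13 digits).
#' @param store a `concept_store`.
#' @return list with `cip_code`, `status` ("mapped"/"unmapped"), `reason`
#'   (for unmapped), and `cip_concept_id`, `atc_concept_id`,
#'   `rxnorm_concept_id` (NA where missing).
#' @export
map_drug <- function(cip_code, store) {
  if (is.na(cip_code) || !grepl("^\\d{7}(\\d{6})?$", cip_code))
    etl_stop("input", "malformed CIP code '%s' (expect 7 or 13 digits)",
             cip_code)
  res <- list(cip_code = cip_code, status = "unmapped", reason = NA_character_,
              cip_concept_id = NA_real_, atc_concept_id = NA_real_,
              rxnorm_concept_id = NA_real_)
  cip <- concept_by_code(store, "CIP", cip_code)
  if (!nrow(cip)) { res$reason <- "unknown CIP code"; return(res) }
  res$cip_concept_id <- cip$concept_id[1]
  atc <- rel_targets(store, cip$concept_id[1], "CIP to ATC")
  if (!length(atc)) { res$reason <- "missing first hop"; return(res) }
  res$atc_concept_id <- atc[1]
  rx <- rel_targets(store, atc[1], "ATC to RxNorm")
  if (!length(rx)) { res$reason <- "missing second hop"; return(res) }
  res$rxnorm_concept_id <- rx[1]
  res$status <- "mapped"
  res$reason <- NA_character_
  res
}

# -- Cohen's kappa ----------------------------------------------------------

#' Chance-corrected inter-annotator agreement (Cohen's unweighted kappa)
#'
#' Observed agreement `p_o` is the fraction of identical paired annotations;
#' chance agreement `p_e` is the sum over categories of the product of the
#' two annotators' marginal proportions; kappa = (p_o - p_e) / (1 - p_e).
#' The statistic ranges over [-1, 1]; kappa is defined as 1 when both
#' annotators agree perfectly and p_e = 1.
#'
#' @param annotations_a,annotations_b equal-length vectors of category
#'   labels (concept choices), at least one item.
#' @return a `kappa_result`: list with `p_o`, `p_e`, `kappa`, `n_items`,
#'   `n_disagreements`.
#' @export
cohen_kappa <- function(annotations_a, annotations_b) {
  a <- as.character(annotations_a); b <- as.character(annotations_b)
  if (length(a) != length(b))
    etl_stop("input", "annotation vectors differ in length (%d vs %d)",
             length(a), length(b))
  if (length(a) < 1)
    etl_stop("input", "need at least one paired annotation")
  n <- length(a)
  p_o <- mean(a == b)
  cats <- union(a, b)
  pa <- tabulate(match(a, cats), length(cats)) / n
  pb <- tabulate(match(b, cats), length(cats)) / n
  p_e <- sum(pa * pb)
  kappa <- if (p_e >= 1) {
    if (p_o == 1) 1 else NA_real_
  } else (p_o - p_e) / (1 - p_e)
  structure(list(p_o = p_o, p_e = p_e, kappa = kappa, n_items = n,
                 n_disagreements = sum(a != b)),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "Cohen's kappa: %.3f  (p_o = %.3f, p_e = %.3f, %d/%d disagreements)\n",
    x$kappa, x$p_o, x$p_e, x$n_disagreements, x$n_items))
  invisible(x)
}
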