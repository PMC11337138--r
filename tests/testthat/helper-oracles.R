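# Independent oracles used to cross-check the package's own computations.

# Brute-force drug-era oracle: union-find over the pairwise relation
# "exposure j starts within exposure i's span extended by the persistence
# window" (transitive closure = the era partition). Returns era intervals
# with exposure counts, ordered by start.
brute_force_eras <- function(starts, ends, window) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (starts[j] >= starts[i] && starts[j] <= ends[i] + window) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    sel <- comp == cc
    data.frame(start = min(starts[sel]), end = max(ends[sel]),
               count = sum(sel))
  }))
  out[order(out$start), , drop = FALSE]
}

# run the package's era derivation on one synthetic exposure stream for a
# drug concept without ingredient links (an ingredient stands for itself)
derive_eras_for_stream <- function(store, starts, ends, window) {
  ing_id <- store$concept$concept_id[
    store$concept$concept_name == "metformin" &
      store$concept$vocabulary_id == "RxNorm Ingredient"]
  origin <- as.Date("2020-01-01")
  exposures <- data.frame(
    drug_exposure_id = seq_along(starts), person_id = 1L,
    drug_concept_id = ing_id,
    drug_exposure_start_date = origin + starts,
    drug_exposure_end_date = origin + ends)
  res <- derive_drug_eras(exposures, store,
                          era_config(persistence_window = window))
  eras <- res$DRUG_ERA
  data.frame(start = as.numeric(eras$drug_era_start_date - origin),
             end = as.numeric(eras$drug_era_end_date - origin),
             count = eras$drug_exposure_count)
}

# Brute-force Cohen's kappa straight from the contingency table
kappa_from_contingency <- function(a, b) {
  u <- union(a, b)
  tab <- table(factor(a, levels = u), factor(b, levels = u))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) return(if (p_o == 1) 1 else NA_real_)
  (p_o - p_e) / (1 - p_e)
}
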