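# Shared helpers: classed conditions, rounding, date handling, XML escaping.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a classed omopetl condition
#'
#' All user-facing errors in the package carry a subclass
#' (`omopetl_<class>_error`) so callers and tests can discriminate
#' configuration errors from, say, integrity errors.
#' @noRd
etl_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("omopetl_", class, "_error"), "omopetl_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Round half away from zero
#'
#' Percentage rounding used throughout coverage reporting. Base `round()`
#' rounds half to even; coverage percentages are rounded half away from zero
#' to one decimal (so 91.45 -> 91.5, not 91.4).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(91.45, 1)  # 91.5
#' round_half_up(-2.5, 0)   # -3
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage n/N rounded to one decimal, half away from zero
#' @param n numerator count.
#' @param N denominator count.
#' @return percentage on the 0-100 scale, one decimal. `NA` when `N` is 0.
#' @export
coverage_percent <- function(n, N) {
  ifelse(N == 0, NA_real_, round_half_up(100 * n / N, 1))
}

# ISO-8601 calendar date helpers -------------------------------------------

as_iso_date <- function(x) as.Date(x, format = "%Y-%m-%d")

is_iso_date_string <- function(x) {
  !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x) &
    !is.na(suppressWarnings(as.Date(x, format = "%Y-%m-%d")))
}

fmt_date <- function(d) format(d, "%Y-%m-%d")

# XML text escaping for the export writer ----------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# Misc ----------------------------------------------------------------------

#' Monotonic identifier sequence
#'
#' One sequence per target table; `next_ids()` hands out `n` fresh integers
#' and advances the counter. Used to allocate artificial primary keys so that
#' no source identifier ever becomes a warehouse key.
#'
#' @param name sequence name (conventionally the target table).
#' @param start first value handed out.
#' @return an `id_sequence` object.
#' @export
id_sequence <- function(name, start = 1L) {
  env <- new.env(parent = emptyenv())
  env$name <- name
  env$next_value <- as.integer(start)
  class(env) <- "id_sequence"
  env
}

#' @rdname id_sequence
#' @param seq an `id_sequence`.
#' @param n how many identifiers to allocate.
#' @export
next_ids <- function(seq, n) {
  stopifnot(inherits(seq, "id_sequence"), n >= 0)
  if (n == 0) return(integer(0))
  ids <- seq(from = seq$next_value, length.out = n)
  seq$next_value <- seq$next_value + as.integer(n)
  as.integer(ids)
}

#' @export
print.id_sequence <- function(x, ...) {
  cat(sprintf("<id_sequence '%s': next = %d>\n", x$name, x$next_value))
  invisible(x)
}

# rbind a list of data.frames sharing columns; returns 0-row template when empty
rbind_all <- function(lst, template = NULL) {
  lst <- Filter(function(d) !is.null(d) && nrow(d) > 0, lst)
  if (length(lst) == 0) return(template)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
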