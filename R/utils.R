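`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric comparisons on serving counts tolerate double rounding, e.g.
# 7 * (2/7) must count as exactly 2 servings/week
.tol <- 1e-9

stop_meddiet <- function(...) stop(..., call. = FALSE)

assert_prob_vector <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop_meddiet("Invalid probability vector for ", what,
                 ": entries must be >= 0 and sum to 1 (got sum = ",
                 format(sum(p), digits = 12), ").")
  }
  invisible(p)
}

#' Significance tier stars for table rendering
#'
#' Maps a raw p-value to the display convention used throughout the
#' result tables: `***` for p < 0.001, `**` for p < 0.01, `*` for
#' p < 0.05, and `""` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of the same length.
#' @export
#' @examples
#' significance_tier(c(0.2, 0.04, 0.004, 2e-4))
significance_tier <- function(p) {
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

# recursively sort list names so hashes are invariant under key reordering
canonicalize <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && any(nzchar(nm))) x <- x[order(nm)]
    x <- lapply(x, canonicalize)
  }
  x
}

numeric_variables <- function(table, exclude = c("participant_id", "location", "class")) {
  nm <- setdiff(names(table), exclude)
  nm[vapply(table[nm], is.numeric, logical(1))]
}
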