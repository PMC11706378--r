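# Shared validation and condition helpers.

ghs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ghsdid_error")))
}

ghs_warn <- function(msg, class = "ghsdid_warning") {
  warning(warningCondition(msg, class = c(class, "ghsdid_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(ok, msg, class = "ghsdid_invalid") {
  if (!isTRUE(ok)) ghs_error(msg, class)
  invisible(TRUE)
}

# Canonical closed vocabularies for country attributes.
income_levels <- function() c("High", "Upper-Middle", "Lower-Middle", "Low")

who_regions <- function() {
  c("Africa", "Americas", "Eastern Mediterranean", "Europe",
    "Southeast Asia", "Western Pacific")
}

governance_indicators <- function() {
  c("gov_effectiveness", "rule_of_law", "control_of_corruption")
}

# Case/whitespace-insensitive matching of a free-text label against a closed
# vocabulary; separators (-, _) are treated as spaces and a trailing
# " income" is ignored so "upper middle income" matches "Upper-Middle".
match_vocab <- function(x, vocab, field) {
  norm <- function(v) {
    v <- tolower(trimws(v))
    v <- gsub("[-_]+", " ", v)
    v <- gsub("\\s+", " ", v)
    sub(" income$", "", v)
  }
  idx <- match(norm(x), norm(vocab))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    ghs_error(sprintf("unknown %s label(s): %s (expected one of %s)",
                      field, paste(shQuote(bad), collapse = ", "),
                      paste(vocab, collapse = ", ")),
              "ghsdid_vocabulary")
  }
  vocab[idx]
}

# Moore-Penrose pseudo-inverse via SVD; returns the inverse and the
# numerical rank so callers can reduce degrees of freedom.
pseudo_inverse <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  rank <- sum(keep)
  if (rank == 0L) {
    return(list(inv = matrix(0, nrow(m), ncol(m)), rank = 0L))
  }
  inv <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  list(inv = inv, rank = rank)
}
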