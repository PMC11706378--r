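# Shared fixture builders: tiny panels, score trees and unit-level data
# constructed in code at test time.

# Coverage data frame for a full country x vaccine x year grid with a
# value function of (country index, vaccine index, year).
grid_coverage <- function(countries, vaccines, years, value_fn) {
  g <- expand.grid(iso3 = countries, vaccine = vaccines, year = years,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$coverage <- value_fn(match(g$iso3, countries),
                         match(g$vaccine, vaccines), g$year)
  g
}

# Attribute table cycling through income groups and regions.
make_attributes <- function(countries, income = NULL, region = NULL) {
  n <- length(countries)
  data.frame(
    iso3 = countries,
    income_group = income %||% rep(c("High", "Upper-Middle", "Lower-Middle",
                                     "Low"), length.out = n),
    who_region = region %||% rep(c("Europe", "Africa", "Americas"),
                                 length.out = n),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small assembled panel: flat coverage plus per-year increments so DiD
# quantities are exactly computable by hand.
flat_panel <- function(n_countries = 8, n_vaccines = 2, years = 2015:2022,
                       base = 80, value_fn = NULL) {
  countries <- sprintf("C%02d", seq_len(n_countries))
  vaccines <- paste0("V", seq_len(n_vaccines))
  value_fn <- value_fn %||% function(ci, vi, yr) base + 0 * ci
  cov <- grid_coverage(countries, vaccines, years, value_fn)
  assemble_panel(cov, make_attributes(countries),
                 panel_config(year_window = range(years),
                              excluded_vaccines = character(0),
                              excluded_countries = character(0)))
}

# Three-level score tree: overall -> 2 categories -> leaves.
small_tree <- function() {
  data.frame(
    node_id = c("overall", "A", "B", "A.1", "A.2", "A.3", "B.1", "B.2"),
    parent_id = c(NA, "overall", "overall", "A", "A", "A", "B", "B"),
    level = c("overall", "category", "category", rep("indicator", 5)),
    stringsAsFactors = FALSE)
}

small_hierarchy <- function(leafs) {
  # leafs: matrix countries x c(A.1, A.2, A.3, B.1, B.2)
  score_hierarchy(small_tree(), leafs)
}

# Independent brute-force evaluation of the doubly-robust 2x2 formula with
# exact cell-level propensities and control cell means (the estimator's
# closed form under a saturated one-factor design).
oracle_dr_att <- function(dy, d, cell) {
  p_cell <- tapply(d, cell, mean)
  p <- p_cell[cell]
  mu_cell <- tapply(dy[!d], cell[!d], mean)
  mu <- mu_cell[cell]
  odds <- p / (1 - p)
  w1 <- d / sum(d)
  w0 <- odds * (!d) / sum(odds * (!d))
  sum((w1 - w0) * (dy - mu))
}
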