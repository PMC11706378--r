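# Reading, validating and assembling the country-vaccine-year coverage panel.

#' Default column mapping for coverage CSV files
#'
#' The default matches the package's own CSV dialect (`iso3`, `vaccine`,
#' `year`, `coverage`); pass a different mapping to [read_coverage()] when
#' reading raw WUENIC exports whose headers differ.
#'
#' @param country,vaccine,year,coverage Column names in the source file.
#' @return A named list usable as the `dialect` argument of
#'   [read_coverage()].
#' @export
coverage_dialect <- function(country = "iso3", vaccine = "vaccine",
                             year = "year", coverage = "coverage") {
  list(country = country, vaccine = vaccine, year = year,
       coverage = coverage)
}

#' Analysis-panel configuration
#'
#' Captures the inclusion/exclusion rules applied when assembling the panel:
#' the study window and the vaccine and country exclusion lists.  The
#' defaults reproduce the study design for WUENIC data: the 2015-2022
#' window, exclusion of yellow fever (YFV, not widely administered) and the
#' first inactivated polio dose (IPV1, unavailable across all years), and
#' exclusion of four countries with substantial missing data (Cook Islands,
#' Niue, State of Palestine, DPR Korea).
#'
#' @param year_window Integer vector of length 2, first and last calendar
#'   year retained.
#' @param excluded_vaccines Character vector of antigen codes to drop.
#' @param excluded_countries Character vector of ISO3 codes to drop.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(year_window = c(2015L, 2022L),
                         excluded_vaccines = c("YFV", "IPV1"),
                         excluded_countries = c("COK", "NIU", "PSE", "PRK")) {
  assert_that(length(year_window) == 2 && year_window[1] <= year_window[2],
              "year_window must be c(first_year, last_year)")
  structure(list(year_window = as.integer(year_window),
                 excluded_vaccines = as.character(excluded_vaccines),
                 excluded_countries = as.character(excluded_countries)),
            class = "panel_config")
}

# Validate (and normalise) a raw coverage data frame.  Used by both
# read_coverage() and assemble_panel() so data frames built in code go
# through the same checks as data read from disk.
validate_coverage_df <- function(df) {
  need <- c("iso3", "vaccine", "year", "coverage")
  assert_that(all(need %in% names(df)),
              paste("coverage table must have columns:",
                    paste(need, collapse = ", ")))
  year_raw <- df$year
  year <- suppressWarnings(as.integer(as.character(year_raw)))
  if (anyNA(year)) {
    ghs_error(sprintf("unparseable year in row(s): %s",
                      paste(utils::head(which(is.na(year)), 5),
                            collapse = ", ")),
              "ghsdid_validation")
  }
  cov_chr <- trimws(as.character(df$coverage))
  blank <- is.na(df$coverage) | cov_chr == ""
  cov <- suppressWarnings(as.numeric(cov_chr))
  bad_parse <- !blank & is.na(cov)
  if (any(bad_parse)) {
    ghs_error(sprintf("unparseable coverage in row(s): %s",
                      paste(utils::head(which(bad_parse), 5),
                            collapse = ", ")),
              "ghsdid_validation")
  }
  out_of_range <- !blank & (cov < 0 | cov > 100)
  if (any(out_of_range)) {
    ghs_error(sprintf("coverage outside [0, 100] in row(s): %s",
                      paste(utils::head(which(out_of_range), 5),
                            collapse = ", ")),
              "ghsdid_validation")
  }
  out <- data.frame(iso3 = as.character(df$iso3),
                    vaccine = as.character(df$vaccine),
                    year = year,
                    coverage = ifelse(blank, NA_real_, cov),
                    is_missing = blank,
                    stringsAsFactors = FALSE)
  key <- paste(out$iso3, out$vaccine, out$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- out[duplicated(key), , drop = FALSE][1, ]
    ghs_error(sprintf("duplicate (country, vaccine, year) key: (%s, %s, %d)",
                      dup$iso3, dup$vaccine, dup$year),
              "ghsdid_duplicate_key")
  }
  out
}

validate_attributes_df <- function(df) {
  need <- c("iso3", "income_group", "who_region")
  assert_that(all(need %in% names(df)),
              paste("attribute table must have columns:",
                    paste(need, collapse = ", ")))
  if (anyDuplicated(df$iso3)) {
    ghs_error("duplicate iso3 in attribute table", "ghsdid_duplicate_key")
  }
  out <- data.frame(iso3 = as.character(df$iso3), stringsAsFactors = FALSE)
  out$income_group <- match_vocab(df$income_group, income_levels(),
                                  "income group")
  out$who_region <- match_vocab(df$who_region, who_regions(), "WHO region")
  for (g in governance_indicators()) {
    if (g %in% names(df)) {
      v <- suppressWarnings(as.numeric(df[[g]]))
      bad <- !is.na(v) & (v < -2.5 | v > 2.5)
      if (any(bad)) {
        ghs_error(sprintf("%s outside [-2.5, 2.5] in row(s): %s", g,
                          paste(utils::head(which(bad), 5), collapse = ", ")),
                  "ghsdid_validation")
      }
      out[[g]] <- v
    }
  }
  out
}

#' Read a coverage CSV into validated observations
#'
#' Each row becomes one country-vaccine-year observation.  Blank coverage
#' cells are kept as explicit missing observations (`is_missing = TRUE`)
#' rather than dropped, so downstream stages decide how to handle them.
#'
#' @param path Path to a CSV file with one row per observation.
#' @param dialect Column mapping, see [coverage_dialect()].
#' @return A data frame with columns `iso3`, `vaccine`, `year`, `coverage`,
#'   `is_missing`.
#' @export
read_coverage <- function(path, dialect = coverage_dialect()) {
  assert_that(file.exists(path), paste("file not found:", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  miss <- setdiff(unlist(dialect), names(raw))
  assert_that(length(miss) == 0,
              paste("columns not found in file:", paste(miss, collapse = ", ")))
  validate_coverage_df(data.frame(iso3 = raw[[dialect$country]],
                                  vaccine = raw[[dialect$vaccine]],
                                  year = raw[[dialect$year]],
                                  coverage = raw[[dialect$coverage]],
                                  stringsAsFactors = FALSE))
}

#' Read a country attribute CSV
#'
#' Expects columns `iso3`, `income_group`, `who_region` and optionally the
#' World Bank governance indicators `gov_effectiveness`, `rule_of_law`,
#' `control_of_corruption` (each on the -2.5..2.5 scale).  Income-group and
#' region labels are matched case- and whitespace-insensitively against the
#' closed vocabularies used throughout the package.
#'
#' @param path Path to a CSV file with one row per country.
#' @return A validated data frame of country attributes.
#' @export
read_attributes <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  validate_attributes_df(utils::read.csv(path, stringsAsFactors = FALSE))
}

new_panel <- function(observations, attributes, year_window, config, log) {
  ord <- order(observations$iso3, observations$vaccine, observations$year)
  observations <- observations[ord, , drop = FALSE]
  rownames(observations) <- NULL
  attributes <- attributes[order(attributes$iso3), , drop = FALSE]
  rownames(attributes) <- NULL
  structure(list(observations = observations,
                 attributes = attributes,
                 year_window = as.integer(year_window),
                 vaccine_set = sort(unique(observations$vaccine)),
                 config = config,
                 log = log),
            class = "coverage_panel")
}

#' Assemble the analysis panel
#'
#' Applies the study's inclusion/exclusion rules to validated coverage and
#' attribute tables: observations outside the year window are dropped,
#' excluded vaccines and countries are removed, and countries present in
#' the coverage data but absent from the attribute table are reported and
#' dropped.  Per-rule exclusion tallies are recorded in the panel log so
#' that `rows_in = rows_kept + sum(rows_excluded_by_rule)` exactly.
#'
#' @param coverage Data frame from [read_coverage()] (or of the same shape).
#' @param attributes Data frame from [read_attributes()] (or same shape).
#' @param config A [panel_config()].
#' @return An object of class `coverage_panel`.
#' @export
assemble_panel <- function(coverage, attributes, config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  cov <- validate_coverage_df(coverage)
  att <- validate_attributes_df(attributes)

  n_in <- nrow(cov)
  in_window <- cov$year >= config$year_window[1] &
    cov$year <= config$year_window[2]
  n_window <- sum(!in_window)
  cov <- cov[in_window, , drop = FALSE]

  vac_excl <- cov$vaccine %in% config$excluded_vaccines
  n_vaccine <- sum(vac_excl)
  cov <- cov[!vac_excl, , drop = FALSE]

  ctry_excl <- cov$iso3 %in% config$excluded_countries
  n_country <- sum(ctry_excl)
  cov <- cov[!ctry_excl, , drop = FALSE]

  no_attr <- !(cov$iso3 %in% att$iso3)
  n_no_attr <- sum(no_attr)
  if (n_no_attr > 0) {
    ghs_warn(sprintf(
      "dropping %d observation(s) from %d country(ies) without attributes: %s",
      n_no_attr, length(unique(cov$iso3[no_attr])),
      paste(utils::head(unique(cov$iso3[no_attr]), 5), collapse = ", ")))
  }
  cov <- cov[!no_attr, , drop = FALSE]

  if (nrow(cov) == 0) {
    ghs_error("panel is empty after applying exclusions",
              "ghsdid_configuration")
  }
  att <- att[att$iso3 %in% cov$iso3, , drop = FALSE]

  log <- list(rows_in = n_in,
              rows_kept = nrow(cov),
              excluded = c(outside_window = n_window,
                           excluded_vaccine = n_vaccine,
                           excluded_country = n_country,
                           no_attributes = n_no_attr),
              n_countries = length(unique(cov$iso3)),
              n_vaccines = length(unique(cov$vaccine)),
              n_missing = sum(cov$is_missing))
  new_panel(cov, att, config$year_window, config, log)
}

#' Summary counts for a panel
#'
#' @param panel A `coverage_panel`.
#' @return A list with country, vaccine, observation and missing-cell
#'   counts; `missing_pct` is the percentage of missing cells rounded to
#'   two decimals (e.g. 12 missing cells on a 191 x 12 x 8 panel give
#'   0.07).
#' @export
panel_summary <- function(panel) {
  stopifnot(inherits(panel, "coverage_panel"))
  obs <- panel$observations
  n <- nrow(obs)
  n_miss <- sum(obs$is_missing)
  list(n_countries = length(unique(obs$iso3)),
       n_vaccines = length(unique(obs$vaccine)),
       n_years = length(unique(obs$year)),
       n_observations = n,
       n_missing = n_miss,
       missing_fraction = n_miss / n,
       missing_pct = round(100 * n_miss / n, 2))
}

#' @export
print.coverage_panel <- function(x, ...) {
  s <- panel_summary(x)
  cat(sprintf("<coverage_panel> %d countries x %d vaccines, %d-%d\n",
              s$n_countries, s$n_vaccines, x$year_window[1],
              x$year_window[2]))
  cat(sprintf("  %d observations (%d missing, %.2f%%)\n",
              s$n_observations, s$n_missing, 100 * s$missing_fraction))
  invisible(x)
}

#' Write a panel to CSV files
#'
#' Writes the observation and attribute tables in the package's CSV dialect
#' (UTF-8, header row, full floating precision).  Re-reading both files with
#' [read_coverage()] / [read_attributes()] and assembling with the panel's
#' own configuration round-trips the panel field-by-field.
#'
#' @param panel A `coverage_panel`.
#' @param coverage_path,attributes_path Output file paths.
#' @return Invisibly, the panel.
#' @export
write_panel <- function(panel, coverage_path, attributes_path) {
  stopifnot(inherits(panel, "coverage_panel"))
  obs <- panel$observations[, c("iso3", "vaccine", "year", "coverage")]
  utils::write.csv(obs, coverage_path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  utils::write.csv(panel$attributes, attributes_path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(panel)
}

# Restrict a panel to a subset of countries (used by the governance sweep).
subset_panel_countries <- function(panel, countries) {
  obs <- panel$observations[panel$observations$iso3 %in% countries, ,
                            drop = FALSE]
  att <- panel$attributes[panel$attributes$iso3 %in% countries, ,
                          drop = FALSE]
  if (nrow(obs) == 0) {
    ghs_error("no observations left after country subset",
              "ghsdid_configuration")
  }
  log <- panel$log
  log$n_countries <- length(unique(obs$iso3))
  new_panel(obs, att, panel$year_window, panel$config, log)
}

#' Load a curated study dataset from a directory
#'
#' Reads `coverage.csv`, `attributes.csv` and (optionally) `scores.csv`
#' from `dir` and assembles the analysis panel.  This is the entry point
#' for reproducing published results from an externally obtained curated
#' dataset laid out in the package's CSV dialect; no data are bundled.
#'
#' @param dir Directory containing the CSV files.
#' @param config A [panel_config()].
#' @return A list with elements `panel` and, when `scores.csv` is present,
#'   `scores` (a long data frame `iso3`, `node_id`, `value`).
#' @export
load_curated_dataset <- function(dir, config = panel_config()) {
  assert_that(dir.exists(dir), paste("directory not found:", dir))
  cov <- read_coverage(file.path(dir, "coverage.csv"))
  att <- read_attributes(file.path(dir, "attributes.csv"))
  out <- list(panel = assemble_panel(cov, att, config))
  score_path <- file.path(dir, "scores.csv")
  if (file.exists(score_path)) {
    out$scores <- utils::read.csv(score_path, stringsAsFactors = FALSE)
  }
  out
}
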