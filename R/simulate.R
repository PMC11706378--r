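# Synthetic-data generator: hierarchical composite scores confounded with
# income group, and a coverage panel following a two-way fixed-effect model
# with common year shocks, planted per-year treatment effects and optional
# pre-trend violations.

#' Generating parameters of a synthetic study panel
#'
#' Encodes the data-generating process
#' \deqn{Coverage_{it} = \alpha + \gamma_t + \delta_i + X_i^\top\beta +
#'   \sum_{t \in post} \tau_t 1[score_i \ge s^*] 1[year = t] + \epsilon_{it}}
#' plus an optional differential pre-2020 slope for treated countries and
#' an income-group-specific post-period shock (`beta_post`), which makes
#' income a genuine time-varying confounder: it shifts both the composite
#' score (through `confounding`) and the pandemic-era coverage drop.
#'
#' Defaults emulate the study panel: 0-100 coverage around a mean in the
#' mid-80s, small country and vaccine effects, a gentle common pre-trend
#' followed by pandemic-era dips, planted effects
#' `tau = (0.74, 1.23, 0.76)` on the scale of the published estimates, and
#' a treatment threshold of 57 on the composite score (roughly the 87th-
#' 90th percentile of the generated score distribution).  With these
#' defaults fewer than 0.1% of cells hit the \[0, 100\] clipping bounds.
#'
#' @param alpha Global intercept (percent coverage).
#' @param year_effects Named vector of common year effects `gamma_t`.
#' @param country_sd SD of country effects `delta_i`.
#' @param vaccine_sd SD of vaccine-level effects.
#' @param tau Named vector of planted post-year treatment effects.
#' @param beta_income,beta_region Named level effects of the covariates.
#' @param beta_post Named income-group-specific additional post-period
#'   shift (the time-varying confounder; all zero removes confounding of
#'   the difference-in-differences).
#' @param noise_sd SD of the observation noise `epsilon_it`.
#' @param score_threshold Score `s*` at or above which `tau` applies.
#' @param confounding Magnitude (score points) of the income-group shift
#'   in sub-indicator means; 0 makes scores independent of income.
#' @param pretrend_slope Differential pre-2020 slope per year for treated
#'   countries (0 = parallel pre-trends).
#' @param seed RNG seed; all randomness in [generate_panel()] flows from
#'   it.
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(alpha = 82,
                            year_effects = c("2015" = 0, "2016" = 0.3,
                                             "2017" = 0.6, "2018" = 0.9,
                                             "2019" = 1.2, "2020" = -2.3,
                                             "2021" = -3.6, "2022" = -2.8),
                            country_sd = 1.5,
                            vaccine_sd = 1.5,
                            tau = c("2020" = 0.74, "2021" = 1.23,
                                    "2022" = 0.76),
                            beta_income = c("High" = 4, "Upper-Middle" = 1,
                                            "Lower-Middle" = -3,
                                            "Low" = -7),
                            beta_region = c("Africa" = -2, "Americas" = 0.5,
                                            "Eastern Mediterranean" = -0.5,
                                            "Europe" = 1,
                                            "Southeast Asia" = -0.5,
                                            "Western Pacific" = 0),
                            beta_post = c("High" = 0, "Upper-Middle" = -1,
                                          "Lower-Middle" = -2, "Low" = -3),
                            noise_sd = 3,
                            score_threshold = 57,
                            confounding = 12,
                            pretrend_slope = 0,
                            seed = 1L) {
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  structure(list(alpha = alpha, year_effects = year_effects,
                 country_sd = country_sd, vaccine_sd = vaccine_sd,
                 tau = tau, beta_income = beta_income,
                 beta_region = beta_region, beta_post = beta_post,
                 noise_sd = noise_sd, score_threshold = score_threshold,
                 confounding = confounding,
                 pretrend_slope = pretrend_slope, seed = as.integer(seed)),
            class = "synthetic_truth")
}

# Deterministic synthetic ISO3-style codes "AAA", "AAB", ...
synthetic_iso3 <- function(n) {
  assert_that(n <= 26^3, "too many countries requested")
  i <- seq_len(n) - 1L
  paste0(LETTERS[i %/% 676L + 1L], LETTERS[(i %/% 26L) %% 26L + 1L],
         LETTERS[i %% 26L + 1L])
}

# Country attributes with study-like margins: income groups and WHO
# regions drawn with the observed 191-country proportions; governance
# indicators correlated with income and with each other, clamped to the
# [-2.5, 2.5] scale.  Consumes RNG state (callers set the seed).
generate_attributes <- function(n_countries) {
  inc_p <- c("High" = 60, "Upper-Middle" = 54, "Lower-Middle" = 48,
             "Low" = 29) / 191
  reg_p <- c("Africa" = 47, "Americas" = 35, "Eastern Mediterranean" = 21,
             "Europe" = 53, "Southeast Asia" = 10,
             "Western Pacific" = 25) / 191
  inc <- sample(names(inc_p), n_countries, replace = TRUE, prob = inc_p)
  reg <- sample(names(reg_p), n_countries, replace = TRUE, prob = reg_p)
  inc_z <- c("High" = 1.2, "Upper-Middle" = 0.3, "Lower-Middle" = -0.4,
             "Low" = -1.1)[inc]
  latent <- stats::rnorm(n_countries, 0, 0.6)
  gov <- function() {
    pmin(pmax(0.8 * inc_z + latent + stats::rnorm(n_countries, 0, 0.3),
              -2.5), 2.5)
  }
  data.frame(iso3 = synthetic_iso3(n_countries),
             income_group = inc, who_region = reg,
             gov_effectiveness = gov(), rule_of_law = gov(),
             control_of_corruption = gov(),
             stringsAsFactors = FALSE)
}

#' Generate hierarchical composite scores
#'
#' Draws sub-indicator values on \[0, 100\] from a Beta-shaped distribution
#' whose country-level mean combines a latent country ability with an
#' income-group shift of magnitude `confounding` (High +c, Upper-Middle
#' +c/3, Lower-Middle -c/3, Low -c score points), then aggregates parents
#' bottom-up by equal-weight means.  `confounding = 0` makes the score
#' distribution independent of income group.  Deterministic per seed.
#'
#' @param attributes Country attribute data frame (needs `iso3`,
#'   `income_group`).
#' @param hierarchy Hierarchy structure, see [default_hierarchy()].
#' @param confounding Income-linked mean shift, in score points.
#' @param base_mean Sub-indicator grand mean, score points.
#' @param country_sd SD of the latent country ability, score points.
#' @param concentration Beta concentration parameter (larger = less
#'   sub-indicator spread).
#' @param seed Optional RNG seed (omit when the caller controls the seed).
#' @return A `score_hierarchy`.
#' @export
generate_scores <- function(attributes, hierarchy = default_hierarchy(),
                            confounding = 12, base_mean = 40,
                            country_sd = 10, concentration = 4,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_structure(hierarchy)
  n <- nrow(attributes)
  shift <- c("High" = 1, "Upper-Middle" = 1 / 3, "Lower-Middle" = -1 / 3,
             "Low" = -1)[attributes$income_group] * confounding
  ability <- stats::rnorm(n, 0, country_sd)
  mu <- pmin(pmax((base_mean + shift + ability) / 100, 0.02), 0.98)
  ch <- children_map(hierarchy)
  leaves <- hierarchy$node_id[lengths(ch)[hierarchy$node_id] == 0]
  leaf_vals <- matrix(0, n, length(leaves),
                      dimnames = list(attributes$iso3, leaves))
  for (j in seq_along(leaves)) {
    leaf_vals[, j] <- 100 * stats::rbeta(n, mu * concentration,
                                         (1 - mu) * concentration)
  }
  score_hierarchy(hierarchy, leaf_vals)
}

#' Generate a synthetic coverage panel
#'
#' Simulates the full study layout: country attributes, composite scores
#' and a country-vaccine-year coverage panel following the model in
#' [synthetic_truth()].  Coverage is clipped to \[0, 100\]; a clipping rate
#' above 1% triggers a warning and above 10% an error (such a
#' parameterization no longer resembles coverage data).
#'
#' @param truth A [synthetic_truth()].
#' @param n_countries,n_vaccines Panel dimensions (defaults 191 and 12, the
#'   study scale).
#' @param years Panel years (default 2015-2022).
#' @param scores Optional named per-country score vector overriding the
#'   hierarchical generator (e.g. uniform scores for threshold-recovery
#'   experiments); names must be left unset to have codes assigned.
#' @param attributes Optional pre-built attribute data frame.
#' @return A list of class `synthetic_study` with elements `panel`
#'   (a `coverage_panel`), `scores` (a `score_hierarchy`, or the supplied
#'   vector), `overall` (named overall score vector), `treated`
#'   (ISO3 codes at or above the threshold) and `truth`.
#' @export
generate_panel <- function(truth = synthetic_truth(), n_countries = 191,
                           n_vaccines = 12, years = 2015:2022,
                           scores = NULL, attributes = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  post_years <- as.integer(names(truth$tau))
  assert_that(sum(years < min(post_years)) >= 2 &&
                sum(years %in% post_years) >= 1,
              "years must span at least two pre and one post period")
  assert_that(all(as.character(years) %in% names(truth$year_effects)),
              "year_effects must cover every panel year")
  set.seed(truth$seed)

  if (is.null(attributes)) attributes <- generate_attributes(n_countries)
  iso3 <- attributes$iso3
  if (is.null(scores)) {
    scores <- generate_scores(attributes, confounding = truth$confounding)
    overall <- score_values(scores)
  } else {
    if (is.null(names(scores))) names(scores) <- iso3
    overall <- scores
  }
  treated <- names(overall)[overall >= truth$score_threshold]

  vaccines <- c("BCG", "DTP1", "DTP3", "HEPB3", "HEPBB", "HIB3", "MCV1",
                "MCV2", "PCV3", "POL3", "ROTAC", "RCV1")
  if (n_vaccines != 12) vaccines <- sprintf("VAC%02d", seq_len(n_vaccines))

  delta <- setNames(stats::rnorm(n_countries, 0, truth$country_sd), iso3)
  vacc_eff <- setNames(stats::rnorm(n_vaccines, 0, truth$vaccine_sd),
                       vaccines)

  grid <- expand.grid(year = as.integer(years), vaccine = vaccines,
                      iso3 = iso3, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  is_post <- grid$year %in% post_years
  is_treated <- grid$iso3 %in% treated
  inc <- attributes$income_group[match(grid$iso3, iso3)]
  reg <- attributes$who_region[match(grid$iso3, iso3)]

  mu <- truth$alpha +
    truth$year_effects[as.character(grid$year)] +
    delta[grid$iso3] +
    vacc_eff[grid$vaccine] +
    truth$beta_income[inc] +
    truth$beta_region[reg] +
    ifelse(is_post, truth$beta_post[inc], 0) +
    ifelse(is_post & is_treated,
           truth$tau[as.character(grid$year)], 0) +
    ifelse(!is_post & is_treated,
           truth$pretrend_slope * (grid$year - (min(post_years) - 1L)), 0)
  y <- mu + stats::rnorm(nrow(grid), 0, truth$noise_sd)

  clipped <- y < 0 | y > 100
  clip_rate <- mean(clipped)
  if (clip_rate > 0.10) {
    ghs_error(sprintf("parameterization forces %.1f%% of cells onto the [0, 100] bounds",
                      100 * clip_rate), "ghsdid_parameter")
  }
  if (clip_rate > 0.01) {
    ghs_warn(sprintf("%.2f%% of coverage values clipped to [0, 100]",
                     100 * clip_rate), "ghsdid_clipping")
  }
  y <- pmin(pmax(y, 0), 100)

  obs <- data.frame(iso3 = grid$iso3, vaccine = grid$vaccine,
                    year = grid$year, coverage = y, is_missing = FALSE,
                    stringsAsFactors = FALSE)
  config <- panel_config(year_window = range(years),
                         excluded_vaccines = character(0),
                         excluded_countries = character(0))
  log <- list(rows_in = nrow(obs), rows_kept = nrow(obs),
              excluded = c(outside_window = 0L, excluded_vaccine = 0L,
                           excluded_country = 0L, no_attributes = 0L),
              n_countries = n_countries, n_vaccines = n_vaccines,
              n_missing = 0L, clip_rate = clip_rate)
  panel <- new_panel(obs, attributes, range(years), config, log)
  structure(list(panel = panel, scores = scores, overall = overall,
                 treated = treated, truth = truth),
            class = "synthetic_study")
}

#' Flag panel cells as missing
#'
#' Marks either an explicit list of (country, vaccine, year) cells or a
#' random fraction of cells as missing (`is_missing = TRUE`, coverage NA).
#' Emulates sparse reporting gaps such as the handful of countries without
#' BCG estimates for 2022.
#'
#' @param panel A `coverage_panel`.
#' @param cells Data frame with columns `iso3`, `vaccine`, `year`; each row
#'   must identify an existing cell.
#' @param rate Alternatively, a random missingness rate in \[0, 0.05\].
#' @param seed RNG seed used with `rate`.
#' @return The panel with the targeted cells flagged missing.
#' @export
inject_missingness <- function(panel, cells = NULL, rate = NULL,
                               seed = NULL) {
  stopifnot(inherits(panel, "coverage_panel"))
  obs <- panel$observations
  if (!is.null(cells)) {
    key <- paste(obs$iso3, obs$vaccine, obs$year, sep = "\r")
    want <- paste(cells$iso3, cells$vaccine, cells$year, sep = "\r")
    idx <- match(want, key)
    if (anyNA(idx)) {
      bad <- cells[is.na(idx), , drop = FALSE][1, ]
      ghs_error(sprintf("cell not in panel: (%s, %s, %s)", bad$iso3,
                        bad$vaccine, bad$year), "ghsdid_lookup")
    }
  } else {
    rate <- rate %||% 0
    assert_that(rate >= 0 && rate <= 0.05,
                "missingness rate must lie in [0, 0.05]")
    if (!is.null(seed)) set.seed(seed)
    idx <- which(stats::runif(nrow(obs)) < rate)
  }
  if (length(idx) > 0) {
    obs$coverage[idx] <- NA_real_
    obs$is_missing[idx] <- TRUE
  }
  panel$observations <- obs
  panel$log$n_missing <- sum(obs$is_missing)
  panel
}
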