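# Doubly-robust 2x2 difference-in-differences: propensity model, outcome
# model, the combined ATT estimator and its influence-function inference.
#
# The estimator for a (base, target) year pair is
#   ATT = sum_i (w1_i - w0_i) (dY_i - mu(X_i)),   dY_i = Y_i,target - Y_i,base
# with w1_i = D_i / sum(D), w0_i proportional to the propensity odds
# p(X_i) / (1 - p(X_i)) over control units and normalised to sum to one,
# and mu(X) the least-squares fit of dY on X among controls.  The estimate
# is consistent if either the propensity model or the outcome model is
# correctly specified; standard errors come from the influence function
# aggregated to country clusters.

# ---- design matrices ------------------------------------------------------

# Dummy-encode categorical covariates with a reference level per factor
# (levels sorted alphabetically, reference = first).  `df` holds one row
# per analysis unit.  With no covariates this is an intercept-only design.
design_matrix <- function(df, covariates) {
  n <- nrow(df)
  if (length(covariates) == 0) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  for (v in covariates) {
    assert_that(v %in% names(df), paste("covariate not found:", v))
    df[[v]] <- factor(df[[v]])
  }
  # constant covariates carry no information beyond the intercept
  covariates <- covariates[vapply(df[covariates], nlevels, 1L) > 1L]
  if (length(covariates) == 0) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  stats::model.matrix(stats::reformulate(covariates), data = df)
}

# ---- component models -----------------------------------------------------

.fit_prop <- function(x, d, clip = c(0.001, 0.999)) {
  if (ncol(x) == 1L) {
    return(list(propensity = rep(mean(d), length(d)), converged = TRUE))
  }
  fit <- suppressWarnings(stats::glm.fit(x, d, family = stats::binomial()))
  p <- pmin(pmax(fit$fitted.values, clip[1]), clip[2])
  list(propensity = p, converged = isTRUE(fit$converged))
}

.fit_outcome <- function(x, d, dy) {
  xc <- x[!d, , drop = FALSE]
  fit <- stats::lm.fit(xc, dy[!d])
  b <- fit$coefficients
  if (anyNA(b)) {
    ghs_warn(sprintf("outcome model design is rank deficient; dropping aliased column(s): %s",
                     paste(names(b)[is.na(b)], collapse = ", ")),
             "ghsdid_rank_deficient")
    b[is.na(b)] <- 0
  }
  list(coefficients = b, fitted = drop(x %*% b))
}

#' Fit the treatment (propensity) model
#'
#' Logistic regression of treatment status on dummy-encoded categorical
#' covariates (reference level = alphabetically first per factor).  Fitted
#' probabilities are clipped to \[0.001, 0.999\], so covariate cells that
#' contain no treated units yield near-zero clipped propensities instead of
#' failing.
#'
#' @param covariates Data frame of categorical covariates (one row per
#'   unit), or a numeric design matrix including an intercept column.
#' @param treated Logical vector of treatment flags.
#' @return List with `propensity` (per-unit probabilities in (0, 1)) and
#'   `converged`.
#' @export
fit_propensity <- function(covariates, treated) {
  treated <- as.logical(treated)
  assert_that(any(treated) && any(!treated),
              "need at least one treated and one control unit",
              "ghsdid_estimation")
  x <- if (is.matrix(covariates)) covariates else
    design_matrix(covariates, names(covariates))
  out <- .fit_prop(x, treated)
  if (!out$converged) {
    ghs_warn("propensity model did not converge (possible separation); fitted values clipped",
             "ghsdid_separation")
  }
  out
}

#' Fit the outcome-change model on control units
#'
#' Least squares of the outcome change `delta_y = Y_target - Y_base` on the
#' dummy design, using control units only; predictions are available for
#' every unit (treated included).  Aliased columns in a rank-deficient
#' design are dropped with a warning.
#'
#' @param covariates Data frame of categorical covariates or a design
#'   matrix (one row per unit, treated and control).
#' @param treated Logical treatment flags.
#' @param delta_y Outcome change per unit.
#' @return List with `coefficients`, `fitted` (predictions for all units)
#'   and `predict(newdata)`.
#' @export
fit_outcome_delta <- function(covariates, treated, delta_y) {
  treated <- as.logical(treated)
  x <- if (is.matrix(covariates)) covariates else
    design_matrix(covariates, names(covariates))
  assert_that(sum(!treated) >= ncol(x),
              "need at least as many control units as design columns",
              "ghsdid_estimation")
  fit <- .fit_outcome(x, treated, delta_y)
  cov_names <- if (is.matrix(covariates)) NULL else names(covariates)
  fit$predict <- function(newdata) {
    nx <- if (is.matrix(newdata)) newdata else
      design_matrix(newdata, cov_names)
    drop(nx[, names(fit$coefficients), drop = FALSE] %*% fit$coefficients)
  }
  fit
}

# ---- the 2x2 estimator ----------------------------------------------------

# Core computation on prepared vectors.  Returns the estimate, the
# cluster-aggregated standard error and the per-unit influence
# contributions (mean zero by construction).
.drdid_core <- function(dy, d, x, cluster) {
  n <- length(dy)
  p <- .fit_prop(x, d)$propensity
  mu <- .fit_outcome(x, d, dy)$fitted
  resid <- dy - mu
  odds <- p / (1 - p)
  ow <- odds * (1 - d)
  att1 <- sum(d * resid) / sum(d)
  att0 <- sum(ow * resid) / sum(ow)
  est <- att1 - att0
  psi <- d * (resid - att1) / mean(d) - ow * (resid - att0) / mean(ow)
  cl <- rowsum(psi, cluster)
  se <- sqrt(sum(cl^2)) / n
  # design weights per cluster (treated share + reweighted control share);
  # their participation ratio is the effective number of clusters used by
  # the small-sample pre-trend reference
  gamma <- rowsum(d / sum(d) + ow / sum(ow), cluster)[, 1]
  list(estimate = est, se = se, influence = psi, n = n,
       n_treated = sum(d), n_control = sum(!d), cluster_weights = gamma)
}

#' Construct an ATT estimate object
#'
#' Container for a single 2x2 ATT: point estimate, influence-function
#' standard error and the normal 95% interval `estimate +/- 1.96 se`.
#' Exposed so externally computed effects (e.g. published table rows) can
#' be assembled and averaged with [average_atts()].
#'
#' @param target_year,base_year Calendar years compared.
#' @param estimate Effect in percentage points of coverage.
#' @param se Standard error.
#' @param influence Optional named per-unit influence contributions.
#' @param cluster Optional cluster id (country) per influence entry.
#' @param n_treated,n_control Unit counts.
#' @param n_dropped Units dropped for missingness in this pair.
#' @param cluster_weights Optional named per-cluster design weights (used
#'   by the pre-trend test's effective-cluster calibration).
#' @return Object of class `att_estimate`.
#' @export
att_estimate <- function(target_year, base_year, estimate, se,
                         influence = NULL, cluster = NULL,
                         n_treated = NA_integer_, n_control = NA_integer_,
                         n_dropped = 0L, cluster_weights = NULL) {
  structure(list(target_year = as.integer(target_year),
                 base_year = as.integer(base_year),
                 estimate = estimate, se = se,
                 ci_lo = estimate - 1.96 * se,
                 ci_hi = estimate + 1.96 * se,
                 influence = influence, cluster = cluster,
                 n_treated = n_treated, n_control = n_control,
                 n_dropped = n_dropped, cluster_weights = cluster_weights),
            class = "att_estimate")
}

#' @export
print.att_estimate <- function(x, ...) {
  cat(sprintf("ATT %d vs %d: %.3f (95%% CI %.3f, %.3f), se %.3f\n",
              x$target_year, x$base_year, x$estimate, x$ci_lo, x$ci_hi,
              x$se))
  invisible(x)
}

# Prepare per-unit structures shared by all year-pair fits: the unit-year
# outcome matrix, the covariate design and the country cluster id.
prepare_units <- function(panel, covariates = c("income_group", "who_region"),
                          unit = c("country_vaccine", "country_mean")) {
  stopifnot(inherits(panel, "coverage_panel"))
  unit <- match.arg(unit)
  obs <- panel$observations[!panel$observations$is_missing, , drop = FALSE]
  years <- sort(unique(panel$observations$year))
  if (unit == "country_mean") {
    agg <- stats::aggregate(coverage ~ iso3 + year, data = obs, FUN = mean)
    obs <- agg
    unit_id <- sort(unique(obs$iso3))
    iso3 <- unit_id
    row_of <- match(obs$iso3, unit_id)
  } else {
    unit_id <- sort(unique(paste(panel$observations$iso3,
                                 panel$observations$vaccine, sep = ":")))
    iso3 <- sub(":.*$", "", unit_id)
    row_of <- match(paste(obs$iso3, obs$vaccine, sep = ":"), unit_id)
  }
  Y <- matrix(NA_real_, length(unit_id), length(years),
              dimnames = list(unit_id, as.character(years)))
  Y[cbind(row_of, match(obs$year, years))] <- obs$coverage
  att <- panel$attributes[match(iso3, panel$attributes$iso3), , drop = FALSE]
  x <- design_matrix(att, covariates)
  list(Y = Y, x = x, iso3 = iso3, unit_id = unit_id, years = years,
       n = length(unit_id), covariates = covariates, unit = unit)
}

# One (base, target) fit on a prepared object.  Units missing either year
# are dropped pairwise; influence contributions are re-scaled to the full
# unit set (zero for dropped units) so fits remain combinable.
.att_pair <- function(prep, treated_iso3, base_year, target_year) {
  yb <- prep$Y[, as.character(base_year)]
  yt <- prep$Y[, as.character(target_year)]
  ok <- !is.na(yb) & !is.na(yt)
  d <- prep$iso3 %in% treated_iso3
  if (sum(d & ok) == 0) {
    ghs_error(sprintf("all treated units dropped for missingness in %d vs %d",
                      target_year, base_year), "ghsdid_estimation")
  }
  if (sum(!d & ok) == 0) {
    ghs_error(sprintf("all control units dropped for missingness in %d vs %d",
                      target_year, base_year), "ghsdid_estimation")
  }
  core <- .drdid_core((yt - yb)[ok], d[ok], prep$x[ok, , drop = FALSE],
                      prep$iso3[ok])
  psi <- setNames(numeric(prep$n), prep$unit_id)
  psi[ok] <- core$influence * (prep$n / core$n)
  cl <- rowsum(psi, prep$iso3)
  att_estimate(target_year, base_year, core$estimate,
               se = sqrt(sum(cl^2)) / prep$n,
               influence = psi, cluster = prep$iso3,
               n_treated = core$n_treated, n_control = core$n_control,
               n_dropped = prep$n - core$n,
               cluster_weights = core$cluster_weights)
}

#' Doubly-robust 2x2 ATT for one pair of years
#'
#' Estimates the average treatment effect on the treated of the cutoff
#' assignment on the change in coverage from `base_year` to `target_year`,
#' combining inverse-probability-of-treatment weighting with
#' outcome-regression adjustment.  Units missing either year are dropped
#' pairwise (tallied in `n_dropped`); variance is clustered at the country
#' level via the influence function.
#'
#' @param panel A `coverage_panel`.
#' @param assignment A [assign_treatment()] result.
#' @param base_year,target_year Years compared.
#' @param covariates Character vector of attribute columns entering both
#'   the propensity and the outcome model (dummy-encoded).
#' @param unit Analysis unit: each country-vaccine series (default) or the
#'   per-country mean across vaccines.
#' @return An [att_estimate()].
#' @export
dr_att_2x2 <- function(panel, assignment, base_year, target_year,
                       covariates = c("income_group", "who_region"),
                       unit = "country_vaccine") {
  stopifnot(inherits(assignment, "treatment_assignment"))
  prep <- prepare_units(panel, covariates, unit)
  .att_pair(prep, assignment$treated, base_year, target_year)
}
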