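# Event-study estimation: yearly post effects, placebo pre effects, the
# pooled 2020-2022 average and the joint parallel pre-trend test.

# Stack influence vectors of several fits into an n x K matrix aligned on
# the shared unit set (fits from one prepared object share units).
influence_matrix <- function(fits) {
  stopifnot(length(fits) >= 1)
  do.call(cbind, lapply(fits, `[[`, "influence"))
}

#' Average several ATT estimates
#'
#' The pooled estimate is the unweighted mean of the component estimates
#' (exactly, so a printed average can be checked against its printed yearly
#' effects); its variance comes from the averaged influence functions,
#' clustered by country.
#'
#' @param fits List of [att_estimate()] objects sharing a unit set.
#' @return An [att_estimate()] whose `target_year`/`base_year` span the
#'   pooled years.
#' @export
average_atts <- function(fits) {
  stopifnot(length(fits) >= 1)
  est <- mean(vapply(fits, `[[`, numeric(1), "estimate"))
  has_inf <- !any(vapply(fits, function(f) is.null(f$influence), logical(1)))
  if (has_inf) {
    psi <- rowMeans(influence_matrix(fits))
    cluster <- fits[[1]]$cluster
    n <- length(psi)
    se <- sqrt(sum(rowsum(psi, cluster)^2)) / n
  } else {
    # independent-components fallback when no influence data are attached
    psi <- NULL
    cluster <- NULL
    se <- sqrt(sum(vapply(fits, `[[`, numeric(1), "se")^2)) /
      length(fits)
  }
  att_estimate(max(vapply(fits, `[[`, integer(1), "target_year")),
               min(vapply(fits, `[[`, integer(1), "base_year")),
               est, se, influence = psi, cluster = cluster,
               n_treated = fits[[1]]$n_treated,
               n_control = fits[[1]]$n_control)
}

# Effective number of clusters: participation ratio of the estimator's
# per-cluster design weights, averaged over the placebo fits.  With few
# treated countries the joint covariance is estimated from far fewer
# effective clusters than countries, which the F reference accounts for.
.effective_clusters <- function(placebos) {
  g <- vapply(placebos, function(f) {
    if (is.null(f$cluster_weights)) return(NA_real_)
    sum(f$cluster_weights)^2 / sum(f$cluster_weights^2)
  }, numeric(1))
  mean(g)
}

.pretrend_wald <- function(placebos, reference = "f") {
  theta <- vapply(placebos, `[[`, numeric(1), "estimate")
  K <- length(theta)
  Phi <- influence_matrix(placebos)
  n <- nrow(Phi)
  S <- rowsum(Phi, placebos[[1]]$cluster)
  V <- crossprod(S) / n^2
  if (max(abs(V)) < 1e-24) {
    if (max(abs(theta)) < 1e-10) {
      return(list(statistic = 0, df = K, p_value = 1, reference = "degenerate"))
    }
    return(list(statistic = Inf, df = K, p_value = 0, reference = "degenerate"))
  }
  G <- .effective_clusters(placebos)
  if (identical(reference, "f") && is.finite(G) && G > K + 1) {
    # small-sample covariance factor, Wishart-style
    V <- V * G / (G - 1)
  } else {
    reference <- "chisq"
  }
  pinv <- pseudo_inverse(V)
  df <- pinv$rank
  if (df < K) {
    ghs_warn(sprintf("singular pre-trend covariance: using pseudo-inverse with %d degrees of freedom",
                     df), "ghsdid_singular")
  }
  W <- drop(t(theta) %*% pinv$inv %*% theta)
  if (identical(reference, "f")) {
    # Hotelling T^2 calibration: W (G - df) / (df (G - 1)) ~ F(df, G - df)
    p <- stats::pf(W * (G - df) / (df * (G - 1)), df, G - df,
                   lower.tail = FALSE)
  } else {
    p <- stats::pchisq(W, df = df, lower.tail = FALSE)
  }
  list(statistic = W, df = df, p_value = p, reference = reference,
       effective_clusters = G)
}

#' Joint test of parallel pre-trends
#'
#' Wald statistic `W = theta' V^-1 theta` over the placebo pre-period
#' effects, with `V` the joint covariance of the placebo estimates built
#' from their stacked influence functions clustered by country, and one
#' degree of freedom per placebo.  By default `W` is referred to a
#' Hotelling-style F distribution whose denominator degrees of freedom are
#' the effective number of clusters (the participation ratio of the
#' estimator's per-cluster design weights): with few treated countries the
#' joint covariance is estimated from far fewer effective clusters than
#' countries, and the plain chi-square reference over-rejects materially.
#' `reference = "chisq"` gives the uncorrected large-sample version.  A
#' singular covariance falls back to a pseudo-inverse with reduced degrees
#' of freedom (warning).
#'
#' @param placebos A `did_fit` (its placebo effects are used) or a list of
#'   [att_estimate()] objects carrying influence contributions.
#' @param reference `"f"` (small-sample calibrated, default) or
#'   `"chisq"`.
#' @return List with `statistic`, `df`, `p_value`, `reference` and, for
#'   the F reference, `effective_clusters`.
#' @export
pretrend_test <- function(placebos, reference = c("f", "chisq")) {
  reference <- match.arg(reference)
  if (inherits(placebos, "did_fit")) placebos <- placebos$placebo_effects
  stopifnot(length(placebos) >= 1)
  ok <- !vapply(placebos, function(f) is.null(f$influence), logical(1))
  assert_that(all(ok), "placebo estimates must carry influence contributions",
              "ghsdid_estimation")
  .pretrend_wald(placebos, reference)
}

# Shared worker: full event-study fit on a prepared unit object.
.estimate_did_prep <- function(prep, assignment) {
  years <- prep$years
  post_years <- sort(intersect(assignment$post_years, years))
  pre_years <- years[years < min(assignment$post_years)]
  assert_that(length(pre_years) >= 2, "need at least two pre-period years",
              "ghsdid_estimation")
  assert_that(length(post_years) >= 1, "need at least one post-period year",
              "ghsdid_estimation")
  base_post <- max(pre_years)
  treated <- assignment$treated

  valid <- TRUE
  reason <- NULL
  fit_one <- function(base, target) {
    tryCatch(.att_pair(prep, treated, base, target),
             error = function(e) e)
  }
  post <- lapply(post_years, function(t) fit_one(base_post, t))
  names(post) <- as.character(post_years)
  placebo_targets <- pre_years[-1]
  placebo <- lapply(placebo_targets, function(t) fit_one(t - 1L, t))
  names(placebo) <- as.character(placebo_targets)

  errs <- c(post, placebo)[vapply(c(post, placebo), inherits, logical(1),
                                  "error")]
  if (length(errs) > 0) {
    valid <- FALSE
    reason <- conditionMessage(errs[[1]])
    avg <- NULL
    pre_test <- list(statistic = NA_real_, df = NA_integer_,
                     p_value = NA_real_)
  } else {
    avg <- average_atts(post)
    pre_test <- .pretrend_wald(placebo)
  }

  n_units_used <- if (valid) post[[1]]$n_treated + post[[1]]$n_control
                  else NA_integer_
  structure(list(post_effects = post,
                 placebo_effects = placebo,
                 average_effect = avg,
                 pretrend = pre_test,
                 pretrend_p = pre_test$p_value,
                 n_treated = length(assignment$treated),
                 n_control = length(assignment$control),
                 n_units = prep$n,
                 n_units_used = n_units_used,
                 cutoff = assignment$cutoff,
                 score_id = assignment$score_id,
                 covariates = prep$covariates,
                 unit = prep$unit,
                 valid = valid, reason = reason),
            class = "did_fit")
}

#' Event-study doubly-robust DiD fit
#'
#' Fits the full event study for a treatment assignment: one doubly-robust
#' 2x2 ATT per post year (2020-2022 by default) against the last
#' pre-pandemic year, one placebo ATT per pre year after the first (each
#' against the preceding year), the pooled post-period average (unweighted
#' mean of the yearly effects, variance from averaged influence functions)
#' and the joint parallel pre-trend p-value.
#'
#' @inheritParams dr_att_2x2
#' @return An object of class `did_fit`.
#' @export
estimate_did <- function(panel, assignment,
                         covariates = c("income_group", "who_region"),
                         unit = "country_vaccine") {
  stopifnot(inherits(assignment, "treatment_assignment"))
  prep <- prepare_units(panel, covariates, unit)
  .estimate_did_prep(prep, assignment)
}

#' @export
print.did_fit <- function(x, ...) {
  cat(sprintf("<did_fit> %s >= %s (%d treated, %d control countries)\n",
              x$score_id, format(x$cutoff), x$n_treated, x$n_control))
  if (!x$valid) {
    cat("  INVALID:", x$reason, "\n")
    return(invisible(x))
  }
  for (nm in names(x$post_effects)) {
    f <- x$post_effects[[nm]]
    cat(sprintf("  %s: %6.2f (%.2f, %.2f)\n", nm, f$estimate, f$ci_lo,
                f$ci_hi))
  }
  cat(sprintf("  average: %.2f (%.2f, %.2f); pre-trend p = %.2f\n",
              x$average_effect$estimate, x$average_effect$ci_lo,
              x$average_effect$ci_hi, x$pretrend_p))
  invisible(x)
}

#' Country-cluster bootstrap standard error of the average effect
#'
#' Resamples countries with replacement (all their analysis units move
#' together), refits the yearly post effects and recomputes the pooled
#' average on each draw.  Provided as a cross-check on the analytic
#' influence-function standard errors, which remain the default inference.
#'
#' @inheritParams dr_att_2x2
#' @param B Number of bootstrap draws.
#' @param seed Optional RNG seed.
#' @return List with `se`, the number of successful draws `B_used`, and the
#'   draws themselves.
#' @export
cluster_bootstrap_se <- function(panel, assignment,
                                 covariates = c("income_group", "who_region"),
                                 unit = "country_vaccine", B = 199,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prep <- prepare_units(panel, covariates, unit)
  countries <- unique(prep$iso3)
  rows_by_country <- split(seq_len(prep$n), prep$iso3)
  post_years <- sort(intersect(assignment$post_years, prep$years))
  base_post <- max(prep$years[prep$years < min(post_years)])
  treated_flag <- countries %in% assignment$treated
  draws <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    pick <- sample(seq_along(countries), replace = TRUE)
    rows <- unlist(rows_by_country[pick], use.names = FALSE)
    # duplicated countries become distinct clusters in the resample
    clus <- rep(seq_along(pick), times = lengths(rows_by_country[pick]))
    d <- rep(treated_flag[pick], times = lengths(rows_by_country[pick]))
    est <- tryCatch({
      ests <- vapply(post_years, function(t) {
        yb <- prep$Y[rows, as.character(base_post)]
        yt <- prep$Y[rows, as.character(t)]
        ok <- !is.na(yb) & !is.na(yt)
        .drdid_core((yt - yb)[ok], d[ok],
                    prep$x[rows, , drop = FALSE][ok, , drop = FALSE],
                    clus[ok])$estimate
      }, numeric(1))
      mean(ests)
    }, error = function(e) NA_real_)
    draws[b] <- est
  }
  ok <- !is.na(draws)
  if (mean(ok) < 0.9) {
    ghs_warn(sprintf("only %d of %d bootstrap draws succeeded", sum(ok), B))
  }
  list(se = stats::sd(draws[ok]), B_used = sum(ok), draws = draws)
}

#' Welch t-test comparing coverage between two year sets
#'
#' Two-sample t-test on observation-level coverage between two periods
#' (e.g. 2015-2019 vs 2022), as used to compare pre-pandemic and recent
#' global means.
#'
#' @param panel A `coverage_panel`.
#' @param period_a,period_b Year vectors defining the two periods.
#' @return List with `t`, `df`, `p_value`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`.
#' @export
compare_period_means <- function(panel, period_a, period_b) {
  stopifnot(inherits(panel, "coverage_panel"))
  obs <- panel$observations[!panel$observations$is_missing, , drop = FALSE]
  xa <- obs$coverage[obs$year %in% period_a]
  xb <- obs$coverage[obs$year %in% period_b]
  assert_that(length(xa) >= 2 && length(xb) >= 2,
              "each period needs at least two observations")
  tt <- stats::t.test(xa, xb)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(xa), mean_b = mean(xb),
       n_a = length(xa), n_b = length(xb))
}
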