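# Sliding-cutoff treatment-assignment sweep with non-degeneracy and
# parallel pre-trend gates, and identification of the minimum qualifying
# cutoff.

#' Gate settings for the cutoff sweep
#'
#' @param min_group Minimum number of treated and of control countries for
#'   a cutoff to be estimable (smaller groups are gated out as
#'   `degenerate_groups`).
#' @param pretrend_alpha Significance level of the parallel pre-trend gate;
#'   a fit with `pretrend_p < pretrend_alpha` is gated as `pretrend_fail`
#'   (the fit is retained for diagnostics).
#' @return A named list.
#' @export
sweep_gates <- function(min_group = 5L, pretrend_alpha = 0.05) {
  assert_that(pretrend_alpha > 0 && pretrend_alpha < 1,
              "pretrend_alpha must be in (0, 1)")
  list(min_group = as.integer(min_group), pretrend_alpha = pretrend_alpha)
}

#' Sliding-cutoff sweep
#'
#' For every cutoff on the grid: assign treatment (`score >= cutoff`),
#' apply the gates, and fit the event-study DiD.  Gate status per cutoff is
#' one of `ok`, `degenerate_groups`, `pretrend_fail` or `fit_error`; a fit
#' is attached iff the status is `ok` or `pretrend_fail`.  The minimum
#' qualifying cutoff is the smallest with status `ok` and a significantly
#' positive effect (see [find_min_qualifying()]).  The sweep is
#' deterministic given its inputs.
#'
#' @param scores Named numeric vector of per-country scores; restricted to
#'   the panel's countries.
#' @param panel A `coverage_panel`.
#' @param covariates Covariate columns for both working models.
#' @param grid Numeric `c(lo, hi, step)`; default the 0-100 score scale in
#'   steps of one.
#' @param gates See [sweep_gates()].
#' @param rule Significance rule declaring a cutoff protective:
#'   `"average"` (pooled post-period CI entirely above zero, the default)
#'   or `"any_year"`.
#' @param post_years Post-period years.
#' @param unit Analysis unit, as in [dr_att_2x2()].
#' @param score_id Label recorded in the result.
#' @return An object of class `sweep_result`.
#' @export
cutoff_sweep <- function(scores, panel,
                         covariates = c("income_group", "who_region"),
                         grid = c(0, 100, 1),
                         gates = sweep_gates(),
                         rule = c("average", "any_year"),
                         post_years = 2020:2022,
                         unit = "country_vaccine",
                         score_id = "overall") {
  rule <- match.arg(rule)
  assert_that(length(grid) == 3 && grid[3] > 0,
              "grid must be c(lo, hi, step) with step > 0")
  panel_countries <- unique(panel$observations$iso3)
  scores <- scores[names(scores) %in% panel_countries]
  assert_that(length(scores) > 0, "no scored countries in the panel")
  if (length(scores) < length(panel_countries)) {
    ghs_warn(sprintf("%d panel country(ies) have no score and are ignored",
                     length(panel_countries) - length(scores)))
  }
  prep <- prepare_units(panel, covariates, unit)
  cutoffs <- round(seq(grid[1], grid[2], by = grid[3]), 10)

  records <- lapply(cutoffs, function(cutoff) {
    pct <- percentile_of_cutoff(scores, cutoff)
    rec <- list(cutoff = cutoff, percentile = pct$percentile,
                percentile_raw = pct$fraction,
                n_treated = sum(scores >= cutoff),
                n_control = sum(scores < cutoff),
                gate_status = NA_character_, fit = NULL)
    assignment <- tryCatch(
      assign_treatment(scores, cutoff, post_years, score_id),
      ghsdid_degenerate = function(e) NULL)
    if (is.null(assignment) ||
        assignment$n_treated < gates$min_group ||
        assignment$n_control < gates$min_group) {
      rec$gate_status <- "degenerate_groups"
      return(rec)
    }
    fit <- tryCatch(.estimate_did_prep(prep, assignment),
                    error = function(e) e)
    if (inherits(fit, "error") || !fit$valid) {
      rec$gate_status <- "fit_error"
      rec$reason <- if (inherits(fit, "error")) conditionMessage(fit)
                    else fit$reason
      return(rec)
    }
    rec$fit <- fit
    rec$gate_status <- if (fit$pretrend_p < gates$pretrend_alpha)
      "pretrend_fail" else "ok"
    rec
  })

  structure(list(score_id = score_id,
                 grid = list(lo = grid[1], hi = grid[2], step = grid[3]),
                 records = records,
                 gates = gates, rule = rule,
                 min_qualifying_cutoff = find_min_qualifying(records, rule)),
            class = "sweep_result")
}

#' Minimum qualifying cutoff
#'
#' Scans gate records in cutoff order and returns the smallest cutoff whose
#' record passed every gate (`gate_status == "ok"`) and whose effect is
#' significantly positive under the chosen rule: the pooled post-period
#' 95% interval entirely above zero (`"average"`), or any yearly post
#' interval entirely above zero (`"any_year"`).
#'
#' @param records List of sweep records (see [cutoff_sweep()]).
#' @param rule `"average"` or `"any_year"`.
#' @return The qualifying cutoff, or `NA_real_` when none qualifies.
#' @export
find_min_qualifying <- function(records, rule = c("average", "any_year")) {
  rule <- match.arg(rule)
  cutoffs <- vapply(records, `[[`, numeric(1), "cutoff")
  for (rec in records[order(cutoffs)]) {
    if (!identical(rec$gate_status, "ok")) next
    sig <- if (rule == "average") {
      rec$fit$average_effect$ci_lo > 0
    } else {
      any(vapply(rec$fit$post_effects, `[[`, numeric(1), "ci_lo") > 0)
    }
    if (isTRUE(sig)) return(as.numeric(rec$cutoff))
  }
  NA_real_
}

#' Sweep over a World Bank governance indicator
#'
#' Same semantics as [cutoff_sweep()] on the governance scale
#' (-2.5..2.5, default step 0.1).  Countries lacking the indicator are
#' dropped with a tally; the sweep requires the indicator for at least 90%
#' of the panel's countries.
#'
#' @param panel A `coverage_panel` whose attributes carry the indicator.
#' @param indicator One of `"gov_effectiveness"`, `"rule_of_law"`,
#'   `"control_of_corruption"`.
#' @param grid Numeric `c(lo, hi, step)` on the governance scale.
#' @inheritParams cutoff_sweep
#' @return A `sweep_result`.
#' @export
sweep_governance <- function(panel, indicator = "gov_effectiveness",
                             covariates = c("income_group", "who_region"),
                             grid = c(-2.5, 2.5, 0.1),
                             gates = sweep_gates(),
                             rule = c("average", "any_year"),
                             post_years = 2020:2022,
                             unit = "country_vaccine") {
  assert_that(indicator %in% names(panel$attributes),
              paste("indicator not present in panel attributes:", indicator))
  gov <- setNames(panel$attributes[[indicator]], panel$attributes$iso3)
  present <- !is.na(gov)
  if (mean(present) < 0.9) {
    ghs_error(sprintf("%s available for only %.0f%% of countries (need >= 90%%)",
                      indicator, 100 * mean(present)),
              "ghsdid_configuration")
  }
  if (any(!present)) {
    ghs_warn(sprintf("dropping %d country(ies) without %s", sum(!present),
                     indicator))
    panel <- subset_panel_countries(panel, names(gov)[present])
  }
  cutoff_sweep(gov[present], panel, covariates, grid, gates, rule,
               post_years, unit, score_id = indicator)
}

#' Tabulate a sweep result
#'
#' One row per cutoff with the per-year and averaged estimates, intervals,
#' pre-trend p-value and gate status (the supplementary-table shape).
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.sweep_result <- function(x, ...) {
  rows <- lapply(x$records, function(rec) {
    out <- data.frame(score_id = x$score_id, cutoff = rec$cutoff,
                      percentile = rec$percentile,
                      n_treated = rec$n_treated,
                      n_control = rec$n_control,
                      gate_status = rec$gate_status,
                      avg_est = NA_real_, avg_lo = NA_real_,
                      avg_hi = NA_real_, est_2020 = NA_real_,
                      lo_2020 = NA_real_, hi_2020 = NA_real_,
                      est_2021 = NA_real_, lo_2021 = NA_real_,
                      hi_2021 = NA_real_, est_2022 = NA_real_,
                      lo_2022 = NA_real_, hi_2022 = NA_real_,
                      pretrend_p = NA_real_, stringsAsFactors = FALSE)
    if (!is.null(rec$fit)) {
      f <- rec$fit
      out$avg_est <- f$average_effect$estimate
      out$avg_lo <- f$average_effect$ci_lo
      out$avg_hi <- f$average_effect$ci_hi
      for (yr in names(f$post_effects)) {
        if (paste0("est_", yr) %in% names(out)) {
          out[[paste0("est_", yr)]] <- f$post_effects[[yr]]$estimate
          out[[paste0("lo_", yr)]] <- f$post_effects[[yr]]$ci_lo
          out[[paste0("hi_", yr)]] <- f$post_effects[[yr]]$ci_hi
        }
      }
      out$pretrend_p <- f$pretrend_p
    }
    out
  })
  do.call(rbind, rows)
}

#' @export
print.sweep_result <- function(x, ...) {
  status <- vapply(x$records, `[[`, character(1), "gate_status")
  cat(sprintf("<sweep_result> %s on [%s, %s] step %s: %d cutoffs (%s)\n",
              x$score_id, format(x$grid$lo), format(x$grid$hi),
              format(x$grid$step), length(x$records),
              paste(names(table(status)), table(status), sep = "=",
                    collapse = ", ")))
  cat("  minimum qualifying cutoff:",
      if (is.na(x$min_qualifying_cutoff)) "none"
      else format(x$min_qualifying_cutoff), "\n")
  invisible(x)
}
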