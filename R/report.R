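# Reporting: group-by-period summaries, local-polynomial trend curves for
# effect-vs-cutoff figures, and formatted result tables.

#' Group-by-period coverage summaries
#'
#' Observation-level mean and SD of coverage for treated, control and all
#' countries over each reporting period (the descriptive-table layout:
#' pre-pandemic 2015-2019, each pandemic year, and the full window), plus
#' income-group and WHO-region cross-tabulations of the assignment.
#'
#' @param panel A `coverage_panel`.
#' @param assignment A [assign_treatment()] result.
#' @param periods Named list of year vectors.
#' @return A list with `coverage` (data frame: group, period, n, mean, sd;
#'   `sd` is NA when a cell has fewer than two observations), `income` and
#'   `region` (count cross-tabs).
#' @export
summarize_groups <- function(panel, assignment,
                             periods = list("2015-2019" = 2015:2019,
                                            "2020" = 2020, "2021" = 2021,
                                            "2022" = 2022,
                                            "2015-2022" = 2015:2022)) {
  stopifnot(inherits(panel, "coverage_panel"),
            inherits(assignment, "treatment_assignment"))
  obs <- panel$observations[!panel$observations$is_missing, , drop = FALSE]
  group_of <- ifelse(obs$iso3 %in% assignment$treated, "treated", "control")
  rows <- list()
  for (g in c("treated", "control", "total")) {
    sel_g <- if (g == "total") rep(TRUE, nrow(obs)) else group_of == g
    for (p in names(periods)) {
      x <- obs$coverage[sel_g & obs$year %in% periods[[p]]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, period = p, n = length(x),
        mean = if (length(x) > 0) mean(x) else NA_real_,
        sd = if (length(x) > 1) stats::sd(x) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  att <- panel$attributes
  grp <- factor(ifelse(att$iso3 %in% assignment$treated, "treated",
                       "control"), levels = c("treated", "control"))
  list(coverage = do.call(rbind, rows),
       income = table(income_group = factor(att$income_group,
                                            income_levels()), group = grp),
       region = table(who_region = factor(att$who_region, who_regions()),
                      group = grp))
}

#' Local-polynomial trend curve with pointwise standard errors
#'
#' Locally weighted polynomial regression (tricube weights, nearest-
#' neighbour bandwidth) of effect estimates on cutoff values, evaluated on
#' the input grid -- the trend curve drawn through effect-vs-cutoff
#' figures.  Fitting uses exact local least squares (no interpolation
#' surface); pointwise standard errors come from the linear-smoother
#' variance form.
#'
#' @param x Cutoff values (at least `degree + 2` distinct points).
#' @param y Effect estimates at each cutoff.
#' @param span Fraction of points in each local window; a span too small
#'   for local fits of the requested degree is widened with a warning.
#' @param degree Local polynomial degree.
#' @return Data frame with columns `x`, `fitted`, `se`.
#' @export
loess_trend <- function(x, y, span = 0.75, degree = 2) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= degree + 2,
              sprintf("need at least %d points for degree %d", degree + 2,
                      degree))
  min_span <- min(1, (degree + 2) / n)
  if (span < min_span) {
    ghs_warn(sprintf("span %.2f too small for local fits; widened to %.2f",
                     span, min_span))
    span <- min_span
  }
  fit <- stats::loess(y ~ x, span = span, degree = degree,
                      control = stats::loess.control(surface = "direct"))
  pred <- stats::predict(fit, newdata = data.frame(x = x), se = TRUE)
  data.frame(x = x, fitted = as.numeric(pred$fit),
             se = as.numeric(pred$se.fit))
}

fmt2 <- function(x) formatC(x, format = "f", digits = 2)

# "0.91* (0.41, 1.41)" -- the table cell convention: two decimals, an
# asterisk when the 95% interval excludes zero.
format_effect_cell <- function(est, lo, hi) {
  if (is.na(est)) return("")
  star <- if (!is.na(lo) && !is.na(hi) && (lo > 0 || hi < 0)) "*" else ""
  sprintf("%s%s (%s, %s)", fmt2(est), star, fmt2(lo), fmt2(hi))
}

#' Render event-study fits as a result table
#'
#' One row per model with the averaged and per-year effects (two decimals,
#' 95% intervals, a `*` marker when an interval excludes zero), the
#' parallel pre-trend p-value and the cutoff with its percentile.
#'
#' @param fits A `did_fit` or list of them.
#' @param labels Optional row labels (defaults to each fit's score id).
#' @param percentiles Optional cutoff percentiles per fit (fractions).
#' @return Data frame of formatted strings plus numeric `avg_est` and
#'   `pretrend_p` columns; zero rows for empty input.
#' @export
render_did_table <- function(fits, labels = NULL, percentiles = NULL) {
  if (inherits(fits, "did_fit")) fits <- list(fits)
  if (length(fits) == 0) {
    return(data.frame(model = character(0), average = character(0),
                      est_2020 = character(0), est_2021 = character(0),
                      est_2022 = character(0), pretrend_p = numeric(0),
                      cutoff = character(0), avg_est = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    lab <- if (!is.null(labels)) labels[i] else f$score_id
    cells <- setNames(rep("", 3), c("2020", "2021", "2022"))
    for (yr in names(f$post_effects)) {
      e <- f$post_effects[[yr]]
      if (yr %in% names(cells)) {
        cells[yr] <- format_effect_cell(e$estimate, e$ci_lo, e$ci_hi)
      }
    }
    avg <- f$average_effect
    cut_cell <- if (is.null(percentiles) || is.na(percentiles[i])) {
      format(f$cutoff)
    } else {
      sprintf("%s (%s)", format(f$cutoff), fmt2(percentiles[i]))
    }
    data.frame(model = lab,
               average = format_effect_cell(avg$estimate, avg$ci_lo,
                                            avg$ci_hi),
               est_2020 = cells[["2020"]], est_2021 = cells[["2021"]],
               est_2022 = cells[["2022"]],
               pretrend_p = round(f$pretrend_p, 2),
               cutoff = cut_cell, avg_est = avg$estimate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a sweep result to CSV
#'
#' Emits the tabulated sweep (see [as.data.frame.sweep_result()]) with a
#' provenance header line (`# ghsdid sweep ...`) recording the score, grid
#' and gates; [read_sweep_csv()] skips the header.
#'
#' @param sweep A `sweep_result`.
#' @param path Output path.
#' @return Invisibly, the written data frame.
#' @export
write_sweep_csv <- function(sweep, path) {
  df <- as.data.frame(sweep)
  header <- sprintf(
    "# ghsdid sweep: score=%s grid=%s:%s:%s min_group=%d pretrend_alpha=%s rule=%s",
    sweep$score_id, format(sweep$grid$lo), format(sweep$grid$hi),
    format(sweep$grid$step), sweep$gates$min_group,
    format(sweep$gates$pretrend_alpha), sweep$rule)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(df)
}

#' Read a sweep CSV written by [write_sweep_csv()]
#'
#' @param path Input path.
#' @return The sweep table data frame.
#' @export
read_sweep_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
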