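test_that("propensity model reproduces cell treatment shares and clips empty cells", {
  # single covariate cell: intercept-only, propensity = treated share
  d <- rep(c(TRUE, FALSE), times = c(3, 7))
  p <- fit_propensity(data.frame(g = rep("x", 10)), d)
  expect_equal(p$propensity, rep(0.3, 10))

  # two cells with treated shares 0.2 and 0.8: saturated logit is exact
  cell <- rep(c("a", "b"), each = 10)
  d2 <- c(rep(c(TRUE, FALSE), times = c(2, 8)),
          rep(c(TRUE, FALSE), times = c(8, 2)))
  p2 <- fit_propensity(data.frame(g = cell), d2)
  expect_equal(unname(p2$propensity[c(1, 11)]), c(0.2, 0.8),
               tolerance = 1e-6)

  # a cell with only controls is clipped at the floor, not an error
  d3 <- c(rep(c(TRUE, FALSE), times = c(5, 5)), rep(FALSE, 10))
  p3 <- suppressWarnings(fit_propensity(data.frame(g = cell), d3))
  expect_equal(unname(p3$propensity[11]), 0.001)

  expect_error(fit_propensity(data.frame(g = cell), rep(FALSE, 20)),
               class = "ghsdid_estimation")
})

test_that("outcome-change model fits control cell means and predicts for all units", {
  cell <- rep(c("a", "b"), each = 6)
  d <- rep(c(TRUE, FALSE, FALSE), 4)
  dy <- ifelse(cell == "a", -1, 3) + ifelse(d, 100, 0)  # treated outliers
  fit <- fit_outcome_delta(data.frame(g = cell), d, dy)
  expect_equal(unname(fit$fitted[c(1, 7)]), c(-1, 3))

  # constant change among controls predicts that constant everywhere
  fit2 <- fit_outcome_delta(data.frame(g = cell), d,
                            ifelse(d, 50, 2.5))
  expect_equal(unname(fit2$fitted), rep(2.5, 12))

  # aliased column (duplicate factor information) -> dropped with warning
  x <- cbind(1, rep(0:1, each = 6), rep(0:1, each = 6))
  colnames(x) <- c("(Intercept)", "b", "b_dup")
  expect_warning(fit3 <- fit_outcome_delta(x, d, dy),
                 class = "ghsdid_rank_deficient")
  expect_equal(unname(fit3$fitted[c(1, 7)]), c(-1, 3))
})

test_that("a noiseless planted effect is recovered exactly with zero standard error", {
  truth <- synthetic_truth(noise_sd = 0,
                           tau = c("2020" = 2, "2021" = 2, "2022" = 2),
                           seed = 5)
  sim <- generate_panel(truth, n_countries = 40, n_vaccines = 3)
  asg <- assign_treatment(sim$overall, truth$score_threshold)
  for (yr in 2020:2022) {
    f <- dr_att_2x2(sim$panel, asg, 2019, yr)
    expect_equal(f$estimate, 2.0, tolerance = 1e-10)
    expect_lt(f$se, 1e-10)
    expect_equal(f$ci_lo, f$estimate, tolerance = 1e-8)
  }
})

test_that("the 2x2 estimator matches a brute-force evaluation on a worked 6-unit panel", {
  # 2 treated, 4 controls in 2 covariate cells; fixed outcome changes
  countries <- sprintf("U%d", 1:6)
  inc <- c("High", "Low", "High", "High", "Low", "Low")
  base <- c(90, 70, 88, 86, 72, 68)
  dy <- c(1.5, -0.5, -1.0, 0.0, -2.0, -3.0)
  cov <- grid_coverage(countries, "V1", 2015:2020, function(ci, vi, yr) {
    base[ci] + ifelse(yr == 2020, dy[ci], 0)
  })
  panel <- assemble_panel(cov, make_attributes(countries, income = inc,
                                               region = "Europe"),
                          panel_config(year_window = c(2015, 2020),
                                       excluded_vaccines = character(0),
                                       excluded_countries = character(0)))
  scores <- setNames(c(80, 80, 10, 10, 10, 10), countries)
  asg <- assign_treatment(scores, 50)
  f <- dr_att_2x2(panel, asg, 2019, 2020, covariates = "income_group")
  d <- countries %in% asg$treated
  expect_equal(f$estimate, oracle_dr_att(dy, d, inc), tolerance = 1e-10)
  expect_equal(f$n_treated, 2)
  expect_equal(f$n_control, 4)
  # influence contributions are mean zero
  expect_lt(abs(mean(f$influence)), 1e-8 * (stats::sd(f$influence) + 1))
})

test_that("with an intercept-only design the estimator reduces to the classical 2x2 DiD", {
  set.seed(404)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    countries <- sprintf("U%02d", 1:n)
    dy <- rnorm(n, 0, 2)
    base <- runif(n, 40, 80)
    cov <- grid_coverage(countries, "V1", 2018:2020, function(ci, vi, yr) {
      base[ci] + ifelse(yr == 2020, dy[ci], 0)
    })
    panel <- assemble_panel(cov, make_attributes(countries),
                            panel_config(year_window = c(2018, 2020),
                                         excluded_vaccines = character(0),
                                         excluded_countries = character(0)))
    d <- seq_len(n) <= n %/% 3
    scores <- setNames(ifelse(d, 90, 10), countries)
    asg <- assign_treatment(scores, 50)
    f <- dr_att_2x2(panel, asg, 2019, 2020, covariates = character(0))
    expect_equal(f$estimate, mean(dy[d]) - mean(dy[!d]), tolerance = 1e-10)
  }
})

test_that("doubly-robust: one misspecified working model leaves the ATT unbiased", {
  # unit-level DGP with an income x region interaction omitted from the
  # working models; n = 5000 units, 200 replicates per scenario
  set.seed(405)
  n <- 5000
  tau <- 1.0
  run_rep <- function(scenario) {
    inc <- sample(c("High", "Low"), n, replace = TRUE)
    reg <- sample(c("Europe", "Africa"), n, replace = TRUE)
    inter <- (inc == "High") & (reg == "Europe")
    if (scenario == "prop_wrong") {
      # true assignment depends on the interaction; outcome model correct
      p_true <- plogis(-1 + 1.5 * inter)
      d <- runif(n) < p_true
      dy <- 2 * (inc == "High") - 1 * (reg == "Africa") + tau * d +
        rnorm(n)
    } else {
      # additive propensity correct; true outcome change has interaction
      p_true <- plogis(-1 + 1 * (inc == "High") - 0.5 * (reg == "Africa"))
      d <- runif(n) < p_true
      dy <- 2 * (inc == "High") - 1 * (reg == "Africa") + 3 * inter +
        tau * d + rnorm(n)
    }
    if (!any(d) || all(d)) return(NA_real_)
    x <- ghsdid:::design_matrix(data.frame(income_group = inc,
                                           who_region = reg),
                                c("income_group", "who_region"))
    ghsdid:::.drdid_core(dy, d, x, cluster = seq_len(n))$estimate
  }
  for (scenario in c("prop_wrong", "outcome_wrong")) {
    est <- vapply(1:200, function(i) run_rep(scenario), numeric(1))
    expect_lt(abs(mean(est, na.rm = TRUE) - tau), 0.1)
  }
})

test_that("averaging pools yearly effects exactly and perfect parallel trends give p = 1", {
  truth <- synthetic_truth(noise_sd = 0, seed = 6)
  sim <- generate_panel(truth, n_countries = 30, n_vaccines = 2)
  asg <- assign_treatment(sim$overall, truth$score_threshold)
  # n = 30 countries leaves one region aliased among controls: expected
  fit <- suppressWarnings(estimate_did(sim$panel, asg))
  ests <- vapply(fit$post_effects, `[[`, numeric(1), "estimate")
  expect_equal(fit$average_effect$estimate, mean(ests), tolerance = 1e-10)
  expect_equal(unname(ests), unname(truth$tau), tolerance = 1e-8)
  # noiseless parallel pre-trends: W = 0, p = 1
  expect_equal(fit$pretrend$statistic, 0)
  expect_equal(fit$pretrend_p, 1)

  # equal yearly effects average to that effect, also with noise
  truth2 <- synthetic_truth(tau = c("2020" = 1.5, "2021" = 1.5,
                                    "2022" = 1.5), seed = 7)
  sim2 <- generate_panel(truth2, n_countries = 60, n_vaccines = 3)
  fit2 <- suppressWarnings(
    estimate_did(sim2$panel, assign_treatment(sim2$overall, 57)))
  ests2 <- vapply(fit2$post_effects, `[[`, numeric(1), "estimate")
  expect_equal(fit2$average_effect$estimate, mean(ests2),
               tolerance = 1e-10)
})

test_that("pre-trend violations are detected and the test degrades gracefully", {
  # a strong differential pre-slope for treated countries is rejected
  truth <- synthetic_truth(pretrend_slope = 1.5, noise_sd = 1, seed = 8)
  sim <- generate_panel(truth, n_countries = 80, n_vaccines = 4)
  fit <- estimate_did(sim$panel,
                      assign_treatment(sim$overall, truth$score_threshold))
  expect_lt(fit$pretrend_p, 0.01)

  # noiseless violation: infinite Wald statistic, p = 0
  truth0 <- synthetic_truth(pretrend_slope = 0.5, noise_sd = 0, seed = 9)
  sim0 <- generate_panel(truth0, n_countries = 30, n_vaccines = 2)
  fit0 <- estimate_did(sim0$panel,
                       assign_treatment(sim0$overall,
                                        truth0$score_threshold))
  expect_equal(fit0$pretrend_p, 0)
})

test_that("period-mean comparisons match the textbook Welch formula", {
  panel <- flat_panel(n_countries = 6, value_fn = function(ci, vi, yr)
    70 + ci + (yr >= 2020) * 2)
  same <- compare_period_means(panel, 2015:2019, 2015:2019)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  # two 3-observation samples, hand-computed Welch statistic
  countries <- c("A1", "A2", "A3")
  cov <- grid_coverage(countries, "V1", 2019:2020, function(ci, vi, yr) {
    c(80, 85, 90, 70, 78, 95)[(yr - 2019) * 3 + ci]
  })
  p2 <- assemble_panel(cov, make_attributes(countries),
                       panel_config(year_window = c(2019, 2020),
                                    excluded_vaccines = character(0),
                                    excluded_countries = character(0)))
  out <- compare_period_means(p2, 2019, 2020)
  xa <- c(80, 85, 90); xb <- c(70, 78, 95)
  t_hand <- (mean(xa) - mean(xb)) /
    sqrt(var(xa) / 3 + var(xb) / 3)
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_error(compare_period_means(p2, integer(0), 2020))
})
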