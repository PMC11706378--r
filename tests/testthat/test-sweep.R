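# Lightweight synthetic sweep records for the qualifying-cutoff scan.
fake_record <- function(cutoff, status, avg_lo = -1, year_los = c(-1, -1, -1)) {
  fit <- NULL
  if (status %in% c("ok", "pretrend_fail")) {
    post <- lapply(seq_along(year_los), function(i) {
      att_estimate(2019L + i, 2019L, year_los[i] + 0.5, 0.25)
    })
    names(post) <- as.character(2020:2022)
    fit <- structure(list(
      post_effects = post,
      average_effect = att_estimate(2022L, 2019L, avg_lo + 0.5, 0.25),
      pretrend_p = if (status == "ok") 0.5 else 0.01,
      valid = TRUE), class = "did_fit")
  }
  list(cutoff = cutoff, percentile = NA_real_, gate_status = status,
       n_treated = NA_integer_, n_control = NA_integer_, fit = fit)
}

test_that("the minimum qualifying cutoff is the smallest ok record with a positive CI", {
  recs <- list(fake_record(57, "ok", avg_lo = 0.4),
               fake_record(58, "ok", avg_lo = 0.2),
               fake_record(65, "ok", avg_lo = 0.1),
               fake_record(50, "pretrend_fail", avg_lo = 2),
               fake_record(40, "degenerate_groups"))
  expect_equal(find_min_qualifying(recs), 57)

  # nothing qualifies
  recs2 <- list(fake_record(10, "degenerate_groups"),
                fake_record(20, "ok", avg_lo = -0.2))
  expect_true(is.na(find_min_qualifying(recs2)))

  # any-year rule
  recs3 <- list(fake_record(30, "ok", avg_lo = -0.5,
                            year_los = c(-1, 0.3, -1)))
  expect_true(is.na(find_min_qualifying(recs3, "average")))
  expect_equal(find_min_qualifying(recs3, "any_year"), 30)
})

test_that("the qualifying scan matches a brute-force scan on random record lists", {
  set.seed(501)
  brute <- function(recs) {
    ok <- vapply(recs, function(r) {
      identical(r$gate_status, "ok") && r$fit$average_effect$ci_lo > 0
    }, logical(1))
    if (!any(ok)) return(NA_real_)
    min(vapply(recs[ok], `[[`, numeric(1), "cutoff"))
  }
  statuses <- c("ok", "pretrend_fail", "degenerate_groups", "fit_error")
  for (rep in 1:1000) {
    n <- sample(1:12, 1)
    recs <- lapply(seq_len(n), function(i) {
      fake_record(cutoff = sample(0:100, 1),
                  status = sample(statuses, 1),
                  avg_lo = runif(1, -1, 1))
    })
    # scan requires sorted records; brute force does not care
    sorted <- recs[order(vapply(recs, `[[`, numeric(1), "cutoff"))]
    expect_identical(find_min_qualifying(sorted), brute(recs))
  }
})

test_that("gates are sound, group sizes are monotone and sweeps are deterministic", {
  truth <- synthetic_truth(seed = 51)
  sim <- generate_panel(truth, n_countries = 80, n_vaccines = 4)
  sw <- suppressWarnings(
    cutoff_sweep(sim$overall, sim$panel, grid = c(0, 100, 5)))

  for (rec in sw$records) {
    if (rec$gate_status == "degenerate_groups") {
      expect_null(rec$fit)
    }
    if (rec$gate_status == "ok") {
      expect_gte(rec$fit$pretrend_p, sw$gates$pretrend_alpha)
    }
    if (rec$gate_status == "pretrend_fail") {
      expect_lt(rec$fit$pretrend_p, sw$gates$pretrend_alpha)
    }
  }
  n_treated <- vapply(sw$records, `[[`, integer(1), "n_treated")
  expect_true(all(diff(n_treated) <= 0))

  # byte-identical serialization across two identical runs
  sw2 <- suppressWarnings(
    cutoff_sweep(sim$overall, sim$panel, grid = c(0, 100, 5)))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(sw, f1)
  write_sweep_csv(sw2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the CSV round-trips through the reader
  back <- read_sweep_csv(f1)
  expect_equal(back$avg_est, as.data.frame(sw)$avg_est, tolerance = 1e-12)
})

test_that("governance sweeps drop unscored countries and degenerate scores gate out", {
  truth <- synthetic_truth(seed = 52)
  sim <- generate_panel(truth, n_countries = 60, n_vaccines = 3)

  # knock out the indicator for a couple of countries: dropped with warning
  panel <- sim$panel
  panel$attributes$gov_effectiveness[1:3] <- NA
  suppressWarnings(
    expect_warning(
      sw <- sweep_governance(panel, "gov_effectiveness",
                             grid = c(-2.5, 2.5, 0.5)),
      "without gov_effectiveness"))
  expect_s3_class(sw, "sweep_result")
  expect_equal(sw$score_id, "gov_effectiveness")

  # indicator missing for >10% of countries: configuration error
  panel$attributes$gov_effectiveness[1:10] <- NA
  expect_error(sweep_governance(panel, "gov_effectiveness"),
               class = "ghsdid_configuration")

  # constant score: every cutoff is degenerate
  panel2 <- sim$panel
  panel2$attributes$gov_effectiveness <- 0.7
  sw2 <- sweep_governance(panel2, "gov_effectiveness",
                          grid = c(-2.5, 2.5, 0.5))
  status <- vapply(sw2$records, `[[`, character(1), "gate_status")
  expect_true(all(status == "degenerate_groups"))
  expect_true(is.na(sw2$min_qualifying_cutoff))
})
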