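test_that("coverage CSVs are parsed, blanks become explicit missing cells, and bad rows error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("iso3,vaccine,year,coverage",
               "AAA,DTP3,2019,95.5",
               "BBB,DTP3,2019,"), path)
  obs <- read_coverage(path)
  expect_equal(nrow(obs), 2)
  expect_equal(obs$coverage[1], 95.5)
  expect_true(obs$is_missing[2])
  expect_true(is.na(obs$coverage[2]))

  writeLines(c("iso3,vaccine,year,coverage", "AAA,DTP3,2019,101"), path)
  expect_error(read_coverage(path), class = "ghsdid_validation")

  writeLines(c("iso3,vaccine,year,coverage", "AAA,DTP3,19xx,90"), path)
  expect_error(read_coverage(path), class = "ghsdid_validation")

  writeLines(c("iso3,vaccine,year,coverage",
               "AAA,DTP3,2019,90", "AAA,DTP3,2019,91"), path)
  expect_error(read_coverage(path), class = "ghsdid_duplicate_key")

  # custom column mapping
  writeLines(c("country,antigen,yr,pct", "AAA,MCV2,2020,77"), path)
  obs <- read_coverage(path, coverage_dialect(country = "country",
                                              vaccine = "antigen",
                                              year = "yr",
                                              coverage = "pct"))
  expect_equal(obs$vaccine, "MCV2")
})

test_that("attribute labels are normalized against closed vocabularies", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("iso3,income_group,who_region,gov_effectiveness",
               "AAA,high,europe,1.2",
               "BBB,upper middle income,eastern mediterranean,-0.4"), path)
  att <- read_attributes(path)
  expect_equal(att$income_group, c("High", "Upper-Middle"))
  expect_equal(att$who_region, c("Europe", "Eastern Mediterranean"))

  writeLines(c("iso3,income_group,who_region", "AAA,High,Oceania"), path)
  expect_error(read_attributes(path), class = "ghsdid_vocabulary")

  writeLines(c("iso3,income_group,who_region,rule_of_law",
               "AAA,High,Europe,3.0"), path)
  expect_error(read_attributes(path), class = "ghsdid_validation")
})

test_that("assembly applies the study exclusions and keeps exact per-rule tallies", {
  # study-shaped input: 195 countries x 14 vaccines x 2014-2022
  countries <- c(sprintf("C%03d", 1:191), "COK", "NIU", "PSE", "PRK")
  vaccines <- c("BCG", "DTP1", "DTP3", "HEPB3", "HEPBB", "HIB3", "MCV1",
                "MCV2", "PCV3", "POL3", "ROTAC", "RCV1", "YFV", "IPV1")
  cov <- grid_coverage(countries, vaccines, 2014:2022,
                       function(ci, vi, yr) 80)
  panel <- assemble_panel(cov, make_attributes(countries), panel_config())
  s <- panel_summary(panel)
  expect_equal(s$n_countries, 191)
  expect_equal(s$n_vaccines, 12)
  expect_equal(s$n_observations, 191 * 12 * 8)
  # counting conservation: rows in = rows kept + per-rule exclusions
  expect_equal(panel$log$rows_in,
               panel$log$rows_kept + sum(panel$log$excluded))

  # identity case: empty exclusion lists leave the panel unchanged
  cfg0 <- panel_config(year_window = c(2014, 2022),
                       excluded_vaccines = character(0),
                       excluded_countries = character(0))
  panel0 <- assemble_panel(cov, make_attributes(countries), cfg0)
  expect_equal(nrow(panel0$observations), nrow(cov))

  # countries without attributes are reported and dropped
  expect_warning(
    p2 <- assemble_panel(cov, make_attributes(countries[1:100]),
                         panel_config()),
    class = "ghsdid_warning")
  expect_equal(panel_summary(p2)$n_countries, 100)

  # everything excluded -> configuration error
  expect_error(
    assemble_panel(cov, make_attributes(countries),
                   panel_config(excluded_vaccines = vaccines)),
    class = "ghsdid_configuration")
})

test_that("assembly is idempotent and round-trips through CSV field-by-field", {
  panel <- flat_panel(n_countries = 6, value_fn = function(ci, vi, yr)
    70 + ci + 0.5 * vi + 0.1 * (yr - 2015))
  cfg <- panel$config
  twice <- assemble_panel(panel$observations, panel$attributes, cfg)
  expect_equal(twice$observations, panel$observations)
  expect_equal(twice$vaccine_set, panel$vaccine_set)

  cov_path <- withr::local_tempfile(fileext = ".csv")
  att_path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, cov_path, att_path)
  back <- assemble_panel(read_coverage(cov_path), read_attributes(att_path),
                         cfg)
  expect_equal(back$observations, panel$observations)
  expect_equal(back$attributes, panel$attributes)
  expect_equal(back$year_window, panel$year_window)
})

test_that("a 191x12x8 panel with 12 missing cells has a 0.07% missing fraction", {
  truth <- synthetic_truth(seed = 11)
  sim <- generate_panel(truth)
  cells <- data.frame(iso3 = sort(unique(sim$panel$observations$iso3))[1:12],
                      vaccine = "BCG", year = 2022)
  panel <- inject_missingness(sim$panel, cells = cells)
  s <- panel_summary(panel)
  expect_equal(s$n_observations, 18336)
  expect_equal(s$n_missing, 12)
  expect_equal(s$missing_pct, 0.07)
})
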