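test_that("scenario configuration validates its design", {
  expect_error(scenario_config(sampling_fraction = 0), "sampling_fraction")
  expect_error(scenario_config(nb_shape_k = -1), "nb_shape_k")
  expect_error(scenario_config(survey_years = 1950), "subset")
  expect_error(scenario_config(
    species = list(bad = list(density = -1, trend = "flat", rate = 0))),
    "density")
  cfg <- scenario_config()
  expect_true(all(cfg$units_per_survey <= cfg$total_units_N))
})

test_that("zero-density species yield all-zero unit counts", {
  cfg <- scenario_config(
    n_counties = 1, county_areas = 5000,
    species = list(gone = list(density = 0, trend = "flat", rate = 0),
                   here = list(density = 1, trend = "flat", rate = 0)),
    seed = 3)
  s <- simulate_survey(cfg, "county1", cfg$survey_years[1])
  expect_true(all(s$units$count[s$units$species == "gone"] == 0))
  expect_gt(sum(s$units$count[s$units$species == "here"]), 0)
})

test_that("unit counts approach the Poisson limit for large shape k", {
  # density 2/km2 on 25 km2 units: mean 50, and variance also ~50 at k=1e6
  cfg <- scenario_config(
    n_counties = 1, county_areas = 25 * 20000, sampling_fraction = 0.5,
    unit_area_cv = 0,
    species = list(w = list(density = 2, trend = "flat", rate = 0)),
    nb_shape_k = 1e6, survey_years = 1990, seed = 5)
  s <- simulate_survey(cfg, 1, 1990)
  cnt <- s$units$count
  expect_gte(length(cnt), 1e4)
  expect_equal(mean(cnt), 50, tolerance = 0.05)
  expect_equal(stats::var(cnt), 50, tolerance = 0.05)
})

test_that("simulated counts show the NB2 variance-mean relationship", {
  cfg <- scenario_config(
    n_counties = 1, county_areas = 25 * 20000, sampling_fraction = 0.5,
    unit_area_cv = 0,
    species = list(w = list(density = 2, trend = "flat", rate = 0)),
    nb_shape_k = 2, survey_years = 1990, seed = 5)
  cnt <- simulate_survey(cfg, 1, 1990)$units$count
  ratio <- stats::var(cnt) / mean(cnt)
  expect_equal(ratio, 1 + 50 / 2, tolerance = 0.1)
})

test_that("generator output is reproducible from (config, seed)", {
  cfg <- scenario_config(seed = 99)
  a <- simulate_survey(cfg, "county2", cfg$survey_years[4])
  b <- simulate_survey(cfg, "county2", cfg$survey_years[4])
  expect_identical(a, b)
  expect_identical(simulate_estimates(cfg), simulate_estimates(cfg))
  expect_identical(simulate_covariates(cfg), simulate_covariates(cfg))
  # different substream for a different county
  expect_false(identical(a$units$count,
                         simulate_survey(cfg, "county1",
                                         cfg$survey_years[4])$units$count))
})

test_that("design errors are rejected", {
  expect_error(
    scenario_config(n_counties = 1, county_areas = 100,
                    sampling_fraction = 1, unit_area_km2 = 60),
    "design error|units_per_survey|sampled units")
  cfg <- scenario_config()
  expect_error(simulate_survey(cfg, "nowhere", cfg$survey_years[1]),
               "unknown county")
  expect_error(simulate_survey(cfg, 1, 1950), "not a survey year")
})

test_that("covariate series follow their generating models", {
  # zero growth -> constant human population
  cfg0 <- scenario_config(human_growth_rate = 0, seed = 2)
  cov0 <- simulate_covariates(cfg0)
  one <- cov0[cov0$county == "county1", ]
  expect_equal(diff(range(one$human_pop)), 0, tolerance = 1e-6)
  # zero noise and nonzero trend -> exactly linear rainfall
  cfg1 <- scenario_config(rain_sd = 0, rain_trend = -1, seed = 2)
  rain <- simulate_covariates(cfg1)
  r1 <- rain$annual_rainfall[rain$county == "county1"]
  expect_equal(diff(r1, differences = 2), rep(0, length(r1) - 2),
               tolerance = 1e-10)
  expect_equal(diff(r1)[1], -1)
  expect_true(all(cov0$annual_rainfall > 0))
  expect_true(all(cov0$human_pop > 0))
})

test_that("OLS on simulated warming series covers the configured slope", {
  # 95% CIs from 500 replicate counties should cover the 0.02 deg C/yr
  # generating slope about 95% of the time
  hits <- vapply(seq_len(500), function(i) {
    cfg <- scenario_config(n_counties = 1, county_areas = 5000,
                           warming = 0.02, temp_sd = 0.3, seed = 10000 + i)
    cov <- simulate_covariates(cfg)
    fit <- stats::lm(tmax_mean ~ year, data = cov)
    ci <- stats::confint(fit)["year", ]
    ci[1] <= 0.02 && 0.02 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)
})

test_that("truth summaries reproduce closed-form period changes", {
  flat <- scenario_config(
    n_counties = 2, county_areas = c(1000, 2000),
    species = list(s = list(density = 1, trend = "flat", rate = 0)))
  tr <- simulate_truth(flat)
  expect_equal(truth_summary(tr, 1977:1980, 2011:2013)$pct_change, 0)

  dec <- scenario_config(
    n_counties = 1, county_areas = 1000,
    species = list(s = list(density = 1, trend = "exponential",
                            rate = -0.0288)))
  trd <- simulate_truth(dec)
  # endpoint years: 39-year decline 1 - exp(-0.0288 * 39) = 67.5%
  pc <- truth_summary(trd, 1977, 2016)$pct_change
  expect_equal(pc, 100 * (exp(-0.0288 * 39) - 1), tolerance = 1e-10)
  expect_equal(pc, -67.5, tolerance = 0.01)

  dbl <- scenario_config(
    n_counties = 1, county_areas = 1000,
    species = list(s = list(density = 1, trend = "exponential",
                            rate = log(2) / 39)))
  expect_equal(truth_summary(simulate_truth(dbl), 1977, 2016)$pct_change,
               100, tolerance = 1e-8)
  expect_error(truth_summary(trd, integer(0), 2011:2013), "empty period")
  expect_error(truth_summary(trd, 1950:1960, 2011:2013), "outside")
})

test_that("scenario round-trips through CSV and YAML", {
  dir <- withr::local_tempdir()
  cfg <- scenario_config(n_counties = 1, county_areas = 2000, seed = 4)
  paths <- write_scenario(cfg, dir)
  expect_true(all(file.exists(paths)))
  units <- utils::read.csv(paths["units"])
  expect_named(units, c("county", "date", "unit_id", "unit_area_km2",
                        "species", "count"))
  yml <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(list(n_counties = 1, county_areas = 2000, seed = 4), yml)
  cfg2 <- scenario_from_yaml(yml)
  expect_equal(cfg2$county_areas, 2000)
  yaml::write_yaml(list(bogus_field = 1), yml)
  expect_error(scenario_from_yaml(yml), "unknown scenario fields")
})
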