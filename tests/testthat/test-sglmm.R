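test_that("NB log-pmf matches closed forms and the Poisson limit", {
  # k = 1 is geometric: P(0) = k/(mu+k) = 1/3 at mu = 2
  expect_equal(exp(nb_logpmf(0, mu = 2, k = 1)), 1 / 3, tolerance = 1e-12)
  # large k: Poisson limit
  y <- 0:40
  expect_equal(nb_logpmf(y, mu = 7.3, k = 1e6),
               stats::dpois(y, 7.3, log = TRUE), tolerance = 1e-4)
  # normalization
  expect_equal(sum(exp(nb_logpmf(0:2000, mu = 12, k = 0.7))), 1,
               tolerance = 1e-8)
  expect_error(nb_logpmf(-1, 1, 1), "nonnegative")
  expect_error(nb_logpmf(2.5, 1, 1), "integers")
})

test_that("design assembly reproduces the 12-species worked dimensions", {
  dates <- narok_calendar()
  expect_length(dates, 34)
  grid <- expand.grid(species = paste0("sp", sprintf("%02d", 1:12)),
                      date = dates, stringsAsFactors = FALSE)
  set.seed(1)
  grid$estimate <- stats::rnbinom(nrow(grid), mu = 500, size = 2) + 1
  md <- assemble_design(grid, spline_spec(20, 3, 3))
  # 34 surveys + 11 unsurveyed years, 12 species
  expect_equal(md$dims$n, (34 + 11) * 12)
  expect_equal(md$dims$n, 540)
  expect_equal(md$dims$ds1, 21)
  expect_equal(md$dims$ds2, 252)
  expect_equal(md$dims$random_total, 273)
  # fixed design: species intercepts + species-by-time slopes = 24 columns
  expect_equal(ncol(md$X), 24)
  md0 <- assemble_design(grid, spline_spec(20, 3, 3),
                         fixed_species_slopes = FALSE)
  expect_equal(ncol(md0$X), 12)
  # placeholder rows exist but are not observations
  expect_equal(sum(md$observed), 34 * 12)
})

test_that("single-species design degenerates as expected", {
  d <- data.frame(species = "only", date = c(1980.4, 1985.4, 1990.4),
                  estimate = c(10, 12, 9))
  md <- assemble_design(d, spline_spec(4, 3, 3))
  expect_equal(md$Z2, md$Z1)      # p = 1: species block equals common block
  d1 <- data.frame(species = "only", date = 1980.4, estimate = 10)
  expect_error(assemble_design(d1, spline_spec(4, 3, 3)), "not estimable")
})

test_that("PQL reduces to a plain NB regression when variances are zero", {
  cfg <- decline_config(seed = 11)
  est <- simulate_estimates(cfg)
  fit0 <- sglmm(estimate ~ species, data = est,
                fixed_species_slopes = FALSE,
                control = sglmm_control(fix_vc = c(0, 0)))
  offs <- log(tapply(est$estimate, est$species, mean))
  df <- data.frame(y = round(est$estimate), sp = factor(est$species),
                   off = offs[est$species])
  oracle <- MASS::glm.nb(y ~ sp - 1 + offset(off), data = df)
  expect_equal(unname(fit0$beta), unname(stats::coef(oracle)),
               tolerance = 1e-6)
})

test_that("a constant single-species series gives a flat trend", {
  d <- data.frame(species = "only",
                  date = seq(1980.45, 2010.45, by = 1),
                  estimate = 250)
  fit <- sglmm(estimate ~ species, data = d, spline = spline_spec(6, 3, 3))
  pr <- predict(fit)
  expect_lt(diff(range(log(pr$fit))), 1e-6)
  expect_equal(fit$sigma2_u1, 1e-10)
  expect_equal(fit$sigma2_u2, 1e-10)
  expect_equal(exp(fit$beta[["only"]] + fit$design$offset[1]), 250,
               tolerance = 1e-6)
})

test_that("exactly three variance components are reported", {
  cfg <- decline_config(seed = 21)
  fit <- sglmm(estimate ~ species, data = simulate_estimates(cfg))
  vc <- summary(fit)$variance_components
  expect_named(vc, c("sigma2_u1", "sigma2_u2", "k"))
  expect_true(all(vc > 0))
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$trace$pql)))
})

test_that("fits are invariant to row order and species relabelling", {
  cfg <- decline_config(seed = 31)
  est <- simulate_estimates(cfg)
  fit <- sglmm(estimate ~ species, data = est)
  perm <- sample(nrow(est))
  fit2 <- sglmm(estimate ~ species, data = est[perm, ])
  expect_equal(predict(fit2)$fit, predict(fit)$fit, tolerance = 1e-8)
  # relabel species (sorted level order changes); fitted values per row of
  # the original data must be unchanged
  relab <- c(a = "w4", b = "w3", c = "w2", d = "w1")
  est3 <- est
  est3$species <- unname(relab[est$species])
  fit3 <- sglmm(estimate ~ species, data = est3)
  p1 <- predict(fit); p3 <- predict(fit3)
  key1 <- paste(relab[p1$species], round(p1$date, 6))
  key3 <- paste(p3$species, round(p3$date, 6))
  expect_equal(p3$fit[match(key1, key3)], p1$fit, tolerance = 1e-8)
})

test_that("the species offset absorbs rescaling of one species", {
  cfg <- decline_config(seed = 41, nb_shape_k = 5)
  est <- simulate_estimates(cfg)
  est$estimate <- round(est$estimate)
  fit <- sglmm(estimate ~ species, data = est)
  est10 <- est
  est10$estimate[est10$species == "b"] <-
    est10$estimate[est10$species == "b"] * 10
  fit10 <- sglmm(estimate ~ species, data = est10)
  pc <- fitted_pct_change(predict(fit), 1977:1980, 2011:2013)
  pc10 <- fitted_pct_change(predict(fit10), 1977:1980, 2011:2013)
  expect_equal(pc10, pc, tolerance = 1e-3)
})

test_that("prediction contracts hold", {
  cfg <- decline_config(seed = 51)
  fit <- sglmm(estimate ~ species, data = simulate_estimates(cfg))
  pr <- predict(fit)
  expect_true(all(pr$lwr <= pr$fit & pr$fit <= pr$upr))
  expect_true(all(pr$fit > 0))
  # observed years are predicted at the survey date, not June
  obs_dates <- unique(fit$design$date[fit$design$observed])
  expect_true(all(pr$date[pr$observed] %in% obs_dates))
  # unsurveyed years sit at mid-June
  expect_true(all(abs(pr$date[!pr$observed] %% 1 - 0.45) < 1e-9))
  expect_error(predict(fit, years = 2030), "extrapolate")
  # excluded rows stay visible in the design but out of the fit
  est <- simulate_estimates(cfg)
  excl <- data.frame(species = est$species[3], date = est$date[3])
  fit_ex <- sglmm(estimate ~ species, data = est, exclude = excl)
  expect_equal(fit_ex$n_fit, fit$n_fit - 1)
  expect_equal(sum(fit_ex$design$observed), sum(fit$design$observed))
})

test_that("simulate() draws NB replicates around the fitted means", {
  cfg <- decline_config(seed = 61, nb_shape_k = 50)
  fit <- sglmm(estimate ~ species, data = simulate_estimates(cfg))
  sims <- simulate(fit, nsim = 200, seed = 1)
  keep <- fit$design$observed & fit$design$include
  mu <- exp(srftrends:::sglmm_linpred(fit, which(keep)))
  simmean <- rowMeans(as.matrix(sims))
  expect_equal(mean(simmean / mu), 1, tolerance = 0.02)
  rs <- residuals(fit, type = "pearson")
  expect_equal(length(rs), fit$n_fit)
})

test_that("95% band has near-nominal pointwise coverage on dense data", {
  sp2 <- list(a = list(density = 2, trend = "exponential", rate = -0.0288),
              b = list(density = 1, trend = "exponential", rate = -0.015))
  cover <- vapply(seq_len(200), function(r) {
    cfg <- scenario_config(n_counties = 1, county_areas = 17000,
                           species = sp2, nb_shape_k = 1e4,
                           survey_years = 1977:2016, seed = 2000 + r)
    fit <- sglmm(estimate ~ species, data = simulate_estimates(cfg))
    m <- merge(predict(fit), simulate_truth(cfg),
               by = c("species", "year"))
    mean(m$abundance >= m$lwr & m$abundance <= m$upr)
  }, numeric(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})
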