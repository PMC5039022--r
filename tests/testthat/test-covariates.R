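test_that("census interpolation is exact at anchors and consistent", {
  expect_equal(interpolate_census(1000, 1960, 8000, 1990, 1960), 1000)
  expect_equal(interpolate_census(1000, 1960, 8000, 1990, 1990), 8000)
  # doubling in 10 years
  expect_equal(interpolate_census(1000, 1960, 2000, 1970, 1970), 2000)
  # Kenya rangeland censuses: 1962 -> 2009 anchors, 1979 interpolant
  p1979 <- interpolate_census(2604900, 1962, 12582028, 2009, 1979)
  expect_equal(p1979, 4.60e6, tolerance = 0.005)
  # chaining through an intermediate year reproduces the direct curve
  direct <- interpolate_census(2604900, 1962, 12582028, 2009, 1995)
  chained <- interpolate_census(p1979, 1979, 12582028, 2009, 1995)
  expect_equal(chained, direct, tolerance = 1e-9)
  expect_error(interpolate_census(-1, 1960, 10, 1970, 1965), "positive")
  expect_error(interpolate_census(10, 1970, 10, 1960, 1965), "precede")
})

test_that("printed human-population growth factors are reproduced", {
  fold <- 12582028 / 2604900
  expect_equal(round(fold, 1), 4.8)
  expect_equal(round(percent_change(2604900, 12582028)), 383)
})

test_that("climate trend test recovers exact and simulated slopes", {
  yr <- 1960:2013
  exact <- suppressWarnings(climate_trend_test(yr, 15 + 0.02 * (yr - 1960)))
  expect_equal(exact$slope, 0.02, tolerance = 1e-12)
  expect_lt(exact$p_value, 1e-12)
  set.seed(2)
  slopes <- replicate(300, {
    climate_trend_test(yr, 15 + 0.02 * (yr - 1960) +
                         stats::rnorm(54, 0, 0.3))$slope
  })
  expect_equal(mean(slopes), 0.02,
               tolerance = 3 * stats::sd(slopes) / sqrt(300) / 0.02)
  expect_error(climate_trend_test(rep(2000, 5), stats::rnorm(5)),
               "distinct years")
})

test_that("type-I error of the trend test is near nominal", {
  set.seed(3)
  rej <- replicate(500,
    climate_trend_test(1960:2013, stats::rnorm(54))$p_value < 0.05)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("NB density regression recovers generating coefficients", {
  set.seed(4)
  hit <- replicate(200, {
    n <- 150
    x <- stats::rnorm(n)
    area <- stats::runif(n, 500, 5000)
    mu <- exp(-4 + 0.4 * x + log(area))
    y <- stats::rnbinom(n, size = 3, mu = mu)
    f <- fit_density_curve(y, x, area, form = "linear")
    se <- summary(f$glm)$coefficients["x", "Std. Error"]
    abs(f$coefficients[["beta"]] - 0.4) <= 2 * se
  })
  expect_gte(mean(hit), 0.90)
  expect_error(fit_density_curve(c(1, 2, 3), rep(1, 3), rep(10, 3)),
               "constant covariate")
})

test_that("AICc prefers the quadratic form when the truth is quadratic", {
  set.seed(5)
  prefer <- replicate(200, {
    n <- 500
    x <- stats::rnorm(n)
    mu <- exp(2 + 0.5 * x - 0.4 * x^2)
    y <- stats::rnbinom(n, size = 3, mu = mu)
    fit_density_curve(y, x, area = rep(1, n), form = "best")$form ==
      "quadratic"
  })
  expect_gte(mean(prefer), 0.90)
})

test_that("peak location matches the closed form and a grid search", {
  f <- list(coefficients = c(intercept = 0, beta = 2, gamma = -0.5))
  expect_equal(peak_location(f)$peak, 2)
  f0 <- list(coefficients = c(intercept = 0, beta = 0, gamma = -0.5))
  expect_equal(peak_location(f0)$peak, 0)
  mono <- list(coefficients = c(intercept = 0, beta = 1, gamma = 0.1))
  pk <- peak_location(mono)
  expect_true(pk$monotone)
  expect_true(is.na(pk$peak))
  set.seed(6)
  for (i in 1:20) {
    beta <- stats::runif(1, -2, 4); gamma <- -stats::runif(1, 0.05, 1)
    grid <- seq(0, 50, by = 0.001)
    dens <- exp(beta * grid + gamma * grid^2)
    found <- grid[which.max(dens)]
    pk <- peak_location(list(coefficients = c(beta = beta,
                                              gamma = gamma)))$peak
    expect_lt(abs(pk - found), 0.002)
  }
})

test_that("constant-variance curve fit recovers exact data", {
  x <- seq(-2, 2, length.out = 50)
  y <- exp(1.2 - 0.5 * x - 0.3 * x^2)
  f <- fit_constant_variance_curve(y, x)
  expect_equal(unname(f$coefficients), c(1.2, -0.5, -0.3), tolerance = 1e-6)
  # flat response
  yflat <- rep(4, 50)
  ff <- fit_constant_variance_curve(yflat, x)
  expect_equal(ff$coefficients[["b0"]], log(4), tolerance = 1e-8)
  expect_equal(ff$coefficients[["b1"]], 0, tolerance = 1e-8)
  expect_equal(ff$coefficients[["b2"]], 0, tolerance = 1e-8)
})

test_that("constant-variance fit agrees with an independent optimizer", {
  requireNamespace("minpack.lm", quietly = TRUE)
  set.seed(7)
  for (i in 1:5) {
    x <- stats::runif(60, 0, 3)
    y <- exp(0.5 + 0.4 * x - 0.25 * x^2) * exp(stats::rnorm(60, 0, 0.1))
    f <- fit_constant_variance_curve(y, x)
    lmfit <- minpack.lm::nlsLM(y ~ exp(b0 + b1 * x + b2 * x^2),
                               data = data.frame(x = x, y = y),
                               start = list(b0 = 0, b1 = 0, b2 = 0))
    expect_equal(f$rss, sum(stats::resid(lmfit)^2), tolerance = 1e-6)
  }
})

test_that("forward selection respects strong hierarchy on random data", {
  set.seed(8)
  for (i in 1:10) {
    n <- 120
    cov <- data.frame(A = stats::rnorm(n), B = stats::rnorm(n),
                      C = stats::rnorm(n))
    y <- stats::rnbinom(n, size = 3,
                        mu = exp(2 + 0.3 * cov$A * cov$B + 0.4 * cov$C))
    fs <- forward_select(y, cov, area = rep(1, n), criterion = "AICc")
    entered <- character(0)
    for (term in fs$selected) {
      if (grepl(":", term)) {
        expect_true(all(strsplit(term, ":")[[1]] %in% entered),
                    label = paste("interaction", term, "after its mains"))
      } else if (grepl("\\^2", term)) {
        expect_true(sub("^I\\((.+)\\^2\\)$", "\\1", term) %in% entered)
      }
      entered <- c(entered, term)
    }
  }
})

test_that("forward selection recovers a known interaction model", {
  set.seed(9)
  found <- replicate(200, {
    n <- 1000
    cov <- data.frame(A = stats::rnorm(n), B = stats::rnorm(n),
                      C = stats::rnorm(n))
    mu <- exp(3 + 0.5 * cov$A + 0.5 * cov$B + 0.5 * cov$A * cov$B)
    y <- stats::rnbinom(n, size = 10, mu = mu)
    fs <- forward_select(y, cov, area = rep(1, n), criterion = "BIC")
    setequal(fs$selected, c("A", "B", "A:B"))
  })
  expect_gte(mean(found), 0.80)
})

test_that("pure-noise responses select at most one effect under BIC", {
  set.seed(10)
  small <- replicate(100, {
    n <- 200
    cov <- data.frame(A = stats::rnorm(n), B = stats::rnorm(n),
                      C = stats::rnorm(n))
    y <- stats::rnbinom(n, size = 3, mu = rep(20, n))
    length(forward_select(y, cov, rep(1, n), criterion = "BIC")$selected) <= 1
  })
  expect_gte(mean(small), 0.90)
})

test_that("standardized fits back-transform to the original scale", {
  set.seed(11)
  n <- 400
  cov <- data.frame(A = stats::rnorm(n, 50, 10), B = stats::rnorm(n, 5, 2))
  mu <- exp(1 + 0.05 * cov$A - 0.2 * cov$B + 0.01 * cov$A * cov$B)
  y <- stats::rnbinom(n, size = 5, mu = mu)
  fs <- forward_select(y, cov, area = rep(1, n), criterion = "AIC")
  cf <- fs$coefficients_original
  eta <- rep(cf[["(Intercept)"]], n)
  if ("A" %in% names(cf)) eta <- eta + cf[["A"]] * cov$A
  if ("B" %in% names(cf)) eta <- eta + cf[["B"]] * cov$B
  if ("A:B" %in% names(cf)) eta <- eta + cf[["A:B"]] * cov$A * cov$B
  if ("I(A^2)" %in% names(cf)) eta <- eta + cf[["I(A^2)"]] * cov$A^2
  if ("I(B^2)" %in% names(cf)) eta <- eta + cf[["I(B^2)"]] * cov$B^2
  expect_equal(eta, unname(stats::predict(fs$final, type = "link")),
               tolerance = 1e-8)
})
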