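#' Intercensal exponential interpolation of human population
#'
#' Between two census anchors \code{(p1, year1)} and \code{(p2, year2)} the
#' population is assumed to grow exponentially at the average annual rate
#' \code{r = log(p2 / p1) / (year2 - year1)}, so
#' \code{P(t) = p1 * exp(r * (t - year1))}.  Exact at both anchors, and
#' multiplicatively consistent across chained anchor pairs.
#'
#' @param p1,p2 positive census populations.
#' @param year1,year2 census years, \code{year1 < year2}.
#' @param target_year year(s) at which to evaluate.
#' @return interpolated population (vectorized over \code{target_year}).
#' @examples
#' interpolate_census(2604900, 1962, 12582028, 2009, 1979)
#' @export
interpolate_census <- function(p1, year1, p2, year2, target_year) {
  if (p1 <= 0 || p2 <= 0) stop("census populations must be positive")
  if (year1 >= year2) stop("year1 must precede year2")
  r <- log(p2 / p1) / (year2 - year1)
  p1 * exp(r * (target_year - year1))
}

#' Linear trend test for a yearly climate series
#'
#' Ordinary least-squares regression of the series on calendar year with a
#' two-sided t-test of the slope.
#'
#' @param year numeric years (at least 3 distinct values).
#' @param value series values (same length).
#' @return list with \code{slope}, \code{se}, \code{t}, \code{p_value},
#'   \code{n}.
#' @export
climate_trend_test <- function(year, value) {
  if (length(year) != length(value)) stop("length mismatch")
  ok <- is.finite(year) & is.finite(value)
  year <- year[ok]; value <- value[ok]
  if (length(unique(year)) < 3)
    stop("need at least 3 distinct years for a trend test")
  fit <- stats::lm(value ~ year)
  sm <- summary(fit)$coefficients
  list(slope = sm["year", "Estimate"], se = sm["year", "Std. Error"],
       t = sm["year", "t value"], p_value = sm["year", "Pr(>|t|)"],
       n = length(year))
}

# AICc with the NB shape counted among the parameters:
# q = number of mean parameters + 1 (shape), n = observations.
aicc_nb <- function(logLik, q, n) {
  if (n - q - 1 <= 0) return(Inf)
  -2 * logLik + 2 * q + 2 * q * (q + 1) / (n - q - 1)
}

#' Negative-binomial density-covariate regression
#'
#' Regresses animal counts on one covariate (linear or quadratic on the log
#' scale) with \code{log(county area)} as offset, so coefficients describe
#' effects on population density.  Fitted by maximum likelihood
#' (\code{MASS::glm.nb}); AICc counts the NB shape among the parameters:
#' \code{AICc = -2 logLik + 2q + 2q(q+1)/(n-q-1)}.
#'
#' With \code{form = "best"} both shapes are fitted and the lower-AICc one
#' returned (the comparison is recorded in the result).
#'
#' @param counts nonnegative integer counts (e.g. rounded estimates).
#' @param covariate numeric covariate, same length.
#' @param area county areas (km2) for the density offset.
#' @param form \code{"linear"}, \code{"quadratic"} or \code{"best"}.
#' @return object of class \code{"density_fit"}: list with
#'   \code{coefficients} (intercept, beta, gamma), \code{theta} (NB shape),
#'   \code{logLik}, \code{AICc}, \code{form}, \code{aicc_table}, and the
#'   underlying \code{glm} object.
#' @export
fit_density_curve <- function(counts, covariate, area,
                              form = c("best", "linear", "quadratic")) {
  form <- match.arg(form)
  if (any(counts < 0)) stop("negative counts")
  if (!all(is.finite(covariate))) stop("covariate must be finite")
  if (stats::sd(covariate) == 0)
    stop("constant covariate: model unidentifiable")
  n <- length(counts)
  df <- data.frame(y = round(counts), x = covariate, off = log(area))
  fit_one <- function(f) {
    fml <- if (f == "linear") y ~ x + offset(off)
           else y ~ x + I(x^2) + offset(off)
    g <- tryCatch(MASS::glm.nb(fml, data = df),
                  error = function(err)
                    stop("NB fit failed (", f, "): ",
                         conditionMessage(err)),
                  warning = function(wr) suppressWarnings(
                    MASS::glm.nb(fml, data = df)))
    q <- length(stats::coef(g)) + 1L
    list(g = g, q = q, aicc = aicc_nb(as.numeric(stats::logLik(g)), q, n))
  }
  forms <- if (form == "best") c("linear", "quadratic") else form
  fits <- lapply(forms, fit_one)
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  best <- which.min(aiccs)
  g <- fits[[best]]$g
  cf <- stats::coef(g)
  coefficients <- c(intercept = unname(cf[1]), beta = unname(cf[2]),
                    gamma = if (length(cf) > 2) unname(cf[3]) else NA_real_)
  structure(list(coefficients = coefficients, theta = g$theta,
                 logLik = as.numeric(stats::logLik(g)),
                 AICc = aiccs[best], form = forms[best],
                 aicc_table = stats::setNames(aiccs, forms), glm = g),
            class = "density_fit")
}

#' @export
print.density_fit <- function(x, ...) {
  cat("NB density-covariate regression (", x$form, " form)\n", sep = "")
  print(x$coefficients)
  cat("theta =", format(x$theta, digits = 4),
      " AICc =", format(x$AICc, digits = 6), "\n")
  invisible(x)
}

#' Peak of a log-quadratic density curve
#'
#' For a fitted quadratic with linear slope beta and quadratic slope gamma,
#' the density peaks at \code{-beta / (2 gamma)} when \code{gamma < 0}.  A
#' negative peak location is reported as 0 (density maximal at zero
#' covariate — the "avoidance" pattern); \code{gamma >= 0} yields no
#' interior peak (\code{NA} with a "monotone" flag), not an error.
#'
#' @param fit a \code{\link{fit_density_curve}} result, or a list with
#'   \code{coefficients} containing \code{beta} and \code{gamma}.
#' @return list with \code{peak} (covariate value or \code{NA}) and
#'   \code{monotone} (logical).
#' @export
peak_location <- function(fit) {
  cf <- fit$coefficients
  beta <- cf[["beta"]]; gamma <- cf[["gamma"]]
  if (is.na(gamma) || gamma >= 0)
    return(list(peak = NA_real_, monotone = TRUE))
  list(peak = max(-beta / (2 * gamma), 0), monotone = FALSE)
}

#' Constant-variance exponential-quadratic curve fit
#'
#' Least-squares fit of \code{response = exp(b0 + b1 x (+ b2 x^2))} with
#' homoscedastic errors — the same mean curve as the NB regression but
#' without its mean-variance coupling, used where the NB confidence bands
#' are too wide to be informative.  Fitted with \code{stats::nls} (port
#' algorithm) from a log-linear least-squares start.
#'
#' @param response nonnegative response (e.g. biomass density).
#' @param covariate numeric covariate.
#' @param form \code{"linear"} (exp-linear) or \code{"quadratic"}.
#' @return object of class \code{"cv_fit"}: \code{coefficients} (b0, b1,
#'   b2), \code{rss}, \code{fitted}, and the \code{nls} object.
#' @export
fit_constant_variance_curve <- function(response, covariate,
                                        form = c("quadratic", "linear")) {
  form <- match.arg(form)
  if (any(response < 0)) stop("negative response")
  df <- data.frame(y = response, x = covariate)
  if (stats::var(response) == 0) {
    # flat response: closed-form least-squares solution
    cf <- c(b0 = log(response[1]), b1 = 0,
            b2 = if (form == "quadratic") 0 else NA_real_)
    return(structure(list(coefficients = cf, rss = 0, fitted = response,
                          form = form, nls = NULL), class = "cv_fit"))
  }
  ylog <- log(pmax(response, max(response) * 1e-6 + 1e-12))
  start_fit <- if (form == "linear") stats::lm(ylog ~ x, df)
               else stats::lm(ylog ~ x + I(x^2), df)
  st <- stats::coef(start_fit)
  st[is.na(st)] <- 0
  if (form == "linear") {
    start <- list(b0 = st[[1]], b1 = st[[2]])
    fml <- y ~ exp(b0 + b1 * x)
  } else {
    start <- list(b0 = st[[1]], b1 = st[[2]], b2 = st[[3]])
    fml <- y ~ exp(b0 + b1 * x + b2 * x^2)
  }
  fit <- tryCatch(
    stats::nls(fml, data = df, start = start, algorithm = "port",
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(err) stop("constant-variance fit diverged: ",
                               conditionMessage(err)))
  cf <- stats::coef(fit)
  coefficients <- c(b0 = unname(cf["b0"]), b1 = unname(cf["b1"]),
                    b2 = if ("b2" %in% names(cf)) unname(cf["b2"])
                         else NA_real_)
  structure(list(coefficients = coefficients,
                 rss = sum(stats::resid(fit)^2),
                 fitted = stats::fitted(fit), form = form, nls = fit),
            class = "cv_fit")
}

#' @export
print.cv_fit <- function(x, ...) {
  cat("Constant-variance exp-", x$form, " fit\n", sep = "")
  print(x$coefficients)
  cat("RSS =", format(x$rss, digits = 6), "\n")
  invisible(x)
}

# Build the candidate effect set: standardized mains, their squares, and all
# pairwise interactions; each with its hierarchy prerequisites.
candidate_effects <- function(mains) {
  eff <- list()
  for (m in mains)
    eff[[m]] <- list(term = m, requires = character(0))
  for (m in mains)
    eff[[paste0("I(", m, "^2)")]] <-
      list(term = paste0("I(", m, "^2)"), requires = m)
  if (length(mains) >= 2) {
    cmb <- utils::combn(sort(mains), 2)
    for (j in seq_len(ncol(cmb)))
      eff[[paste0(cmb[1, j], ":", cmb[2, j])]] <-
        list(term = paste0(cmb[1, j], ":", cmb[2, j]),
             requires = cmb[, j])
  }
  eff
}

#' Forward model selection under strong hierarchy
#'
#' Selects, from six (or fewer) main effects, their squares and all pairwise
#' interactions, the subset of covariates most strongly associated with a
#' count response, by forward selection on an information criterion.  Main
#' effects are internally centered and scaled before fitting; coefficients
#' of the final model are reported on the original scale.  Strong hierarchy
#' is enforced: a square or interaction is eligible only when all its
#' constituent main effects are already in the model.  Ties are broken by
#' larger criterion improvement, then alphabetically.
#'
#' Fits are negative-binomial regressions with log link and
#' \code{log(area)} offset (\code{MASS::glm.nb}).
#'
#' @param counts nonnegative integer counts.
#' @param covariates data.frame of candidate main effects (numeric columns).
#' @param area county areas for the density offset.
#' @param criterion \code{"AICc"}, \code{"AIC"} or \code{"BIC"}.
#' @return object of class \code{"forward_selection"}: \code{selected}
#'   (terms in entry order), \code{trace} (per-step criterion values),
#'   \code{final} (the final \code{glm.nb} fit on standardized scale),
#'   \code{coefficients_original} (final coefficients back-transformed to
#'   the original covariate scale), \code{criterion}.
#' @export
forward_select <- function(counts, covariates, area,
                           criterion = c("AICc", "AIC", "BIC")) {
  criterion <- match.arg(criterion)
  n <- length(counts)
  stopifnot(nrow(covariates) == n)
  mains <- sort(names(covariates))
  ctr <- vapply(covariates, mean, numeric(1))
  scl <- vapply(covariates, stats::sd, numeric(1))
  if (any(scl == 0)) stop("constant covariate: ",
                          paste(mains[scl == 0], collapse = ", "))
  std <- as.data.frame(scale(covariates[mains]))
  std$.y <- round(counts)
  std$.off <- log(area)

  crit_value <- function(g) {
    ll <- as.numeric(stats::logLik(g))
    q <- length(stats::coef(g)) + 1L
    switch(criterion,
           AIC = -2 * ll + 2 * q,
           AICc = aicc_nb(ll, q, n),
           BIC = -2 * ll + q * log(n))
  }
  fit_terms <- function(terms) {
    fml <- if (length(terms))
      stats::as.formula(paste(".y ~", paste(terms, collapse = " + "),
                              "+ offset(.off)"))
    else stats::as.formula(".y ~ 1 + offset(.off)")
    suppressWarnings(MASS::glm.nb(fml, data = std))
  }
  effects <- candidate_effects(mains)
  current <- character(0)
  g <- fit_terms(current)
  best_crit <- crit_value(g)
  trace <- data.frame(step = 0L, added = "(none)", criterion = best_crit,
                      stringsAsFactors = FALSE)
  repeat {
    mains_in <- intersect(current, mains)
    eligible <- Filter(function(ef)
      !(ef$term %in% current) && all(ef$requires %in% mains_in), effects)
    if (!length(eligible)) break
    cand <- vapply(eligible, function(ef) {
      gg <- tryCatch(fit_terms(c(current, ef$term)),
                     error = function(e) NULL)
      if (is.null(gg)) Inf else crit_value(gg)
    }, numeric(1))
    names(cand) <- vapply(eligible, `[[`, character(1), "term")
    imp <- best_crit - cand
    if (max(imp) <= 0) break
    winners <- names(cand)[imp == max(imp)]
    add <- sort(winners)[1]
    current <- c(current, add)
    best_crit <- cand[[add]]
    trace <- rbind(trace, data.frame(step = nrow(trace), added = add,
                                     criterion = best_crit,
                                     stringsAsFactors = FALSE))
  }
  final <- fit_terms(current)
  structure(list(selected = current, trace = trace, final = final,
                 coefficients_original =
                   unstandardize_coefs(stats::coef(final), mains, ctr, scl),
                 criterion = criterion, center = ctr, scale = scl),
            class = "forward_selection")
}

# Map coefficients of a model in standardized covariates x* = (x - c)/s back
# to the original scale, for models with mains, squares and pairwise
# interactions of the standardized variables.
unstandardize_coefs <- function(cf, mains, ctr, scl) {
  out <- c("(Intercept)" = unname(cf["(Intercept)"]))
  add <- function(name, val) {
    out[name] <<- if (name %in% names(out)) out[[name]] + val else val
  }
  for (nm in setdiff(names(cf), "(Intercept)")) {
    v <- cf[[nm]]
    if (nm %in% mains) {             # b * (x-c)/s
      add(nm, v / scl[[nm]])
      add("(Intercept)", -v * ctr[[nm]] / scl[[nm]])
    } else if (grepl("^I\\(.+\\^2\\)$", nm)) {
      m <- sub("^I\\((.+)\\^2\\)$", "\\1", nm)
      s <- scl[[m]]; c0 <- ctr[[m]]
      add(paste0("I(", m, "^2)"), v / s^2)
      add(m, -2 * v * c0 / s^2)
      add("(Intercept)", v * c0^2 / s^2)
    } else if (grepl(":", nm)) {
      ab <- strsplit(nm, ":")[[1]]
      sa <- scl[[ab[1]]]; sb <- scl[[ab[2]]]
      ca <- ctr[[ab[1]]]; cb <- ctr[[ab[2]]]
      add(nm, v / (sa * sb))
      add(ab[1], -v * cb / (sa * sb))
      add(ab[2], -v * ca / (sa * sb))
      add("(Intercept)", v * ca * cb / (sa * sb))
    } else stop("cannot back-transform term: ", nm)
  }
  out
}

#' @export
print.forward_selection <- function(x, ...) {
  cat("Forward selection (", x$criterion, ", strong hierarchy)\n", sep = "")
  if (!length(x$selected)) cat("  no effect entered the model\n")
  else cat("  entered: ", paste(x$selected, collapse = " -> "), "\n",
           sep = "")
  invisible(x)
}
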