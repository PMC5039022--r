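#' Negative-binomial log probability mass
#'
#' NB2 parameterization: mean \code{mu}, shape \code{k}, variance
#' \code{mu * (1 + mu / k)}.  Computed through log-gamma for overflow
#' safety.
#'
#' @param y nonnegative integer counts.
#' @param mu positive means.
#' @param k positive shape parameter.
#' @return log P(Y = y), vectorized.
#' @examples
#' exp(nb_logpmf(0, mu = 2, k = 1)) # 1/3: geometric special case
#' @export
nb_logpmf <- function(y, mu, k) {
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("'y' must contain nonnegative integers")
  if (any(mu <= 0) || any(k <= 0)) stop("'mu' and 'k' must be positive")
  lgamma(y + k) - lgamma(k) - lgamma(y + 1) +
    y * (log(mu) - log(mu + k)) + k * (log(k) - log(mu + k))
}

#' Control parameters for the PQL fitter
#'
#' @param maxit maximum outer iterations.
#' @param tol relative-change convergence tolerance on all parameters
#'   (intercepts, spline coefficients, variance components, NB shape).
#' @param k_init initial NB shape.
#' @param vc_init initial variance components.
#' @param vc_min lower clamp for variance components.
#' @param vc_snap threshold below which a variance component is snapped to
#'   the clamp (negligible on the log-link scale, where the linear predictor
#'   is O(1)); avoids interminable geometric decay toward the boundary.
#' @param k_range allowed range for the moment-matched NB shape.
#' @param fix_vc optional length-2 numeric: hold the two spline variance
#'   components fixed at these values instead of estimating them.  A value
#'   of 0 removes that random-effect block exactly, reducing the fit to a
#'   penalized (or, with both 0, plain) NB regression.
#' @return list of class \code{"sglmm_control"}.
#' @export
sglmm_control <- function(maxit = 2000L, tol = 1e-6, k_init = 1,
                          vc_init = 0.1, vc_min = 1e-10, vc_snap = 1e-6,
                          k_range = c(1e-3, 1e7), fix_vc = NULL) {
  if (!is.null(fix_vc)) stopifnot(length(fix_vc) == 2, all(fix_vc >= 0))
  structure(list(maxit = as.integer(maxit), tol = tol, k_init = k_init,
                 vc_init = vc_init, vc_min = vc_min, vc_snap = vc_snap,
                 k_range = k_range, fix_vc = fix_vc),
            class = "sglmm_control")
}

#' Assemble the trend-model design matrices
#'
#' Builds the observation grid and model matrices of the multivariate
#' semiparametric model: one row per species and grid date, where the grid
#' contains every observed survey date plus a mid-June placeholder for each
#' calendar year without a survey.  The fixed design holds species
#' indicator columns (no global intercept); the random designs are the
#' common-trend P-spline block \code{Z1} (ds1 columns) and the
#' species-specific block-diagonal P-spline \code{Z2} (ds1 x p columns).
#' The per-species offset is the log of the mean included estimate of that
#' species.
#'
#' @param data data.frame with columns \code{species}, \code{date} (decimal
#'   years), \code{estimate}, and optionally \code{include} (logical;
#'   defaults to all \code{TRUE}) and \code{county}.
#' @param spec a \code{\link{spline_spec}}; its domain defaults to the range
#'   of grid dates.
#' @param years calendar years the model must cover (default: full span of
#'   the observed dates); years without surveys get June placeholder rows.
#' @param fixed_species_slopes if \code{TRUE}, adds per-species linear time
#'   fixed effects (the q = p "species x time" columns), doubling the fixed
#'   design width to p + q.
#' @param june fraction of the year for placeholder dates (default 0.45,
#'   mid-June).
#' @return list with elements \code{X}, \code{Z1}, \code{Z2}, \code{offset},
#'   \code{y} (rounded response), \code{y_raw}, \code{observed},
#'   \code{include}, \code{species}, \code{date}, \code{year},
#'   \code{species_levels}, \code{spec}, \code{dims}.
#' @export
assemble_design <- function(data, spec = spline_spec(), years = NULL,
                            fixed_species_slopes = TRUE, june = 0.45) {
  need <- c("species", "date", "estimate")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  if (is.null(data$include)) data$include <- TRUE
  if (length(unique(data$date)) < 2)
    stop("not estimable: need at least 2 distinct survey dates")

  # drop species with no positive included estimate (offset undefined)
  offs_mean <- tapply(data$estimate[data$include],
                      data$species[data$include], mean)
  dead <- names(offs_mean)[!is.finite(log(offs_mean))]
  if (length(dead)) {
    message("excluding species with all-zero estimates: ",
            paste(dead, collapse = ", "))
    data <- data[!data$species %in% dead, , drop = FALSE]
    offs_mean <- offs_mean[setdiff(names(offs_mean), dead)]
  }
  if (!nrow(data)) stop("no usable species left")

  sp_levels <- sort(unique(data$species))
  p <- length(sp_levels)
  obs_dates <- sort(unique(data$date))
  if (is.null(years))
    years <- seq(floor(min(obs_dates)), floor(max(obs_dates)))
  missing_years <- setdiff(years, unique(floor(obs_dates)))
  grid_dates <- sort(c(obs_dates, missing_years + june))

  if (is.null(spec$domain)) spec$domain <- range(grid_dates)

  # one row per species x grid date; attach observations where present
  n_dates <- length(grid_dates)
  df <- data.frame(
    species = rep(sp_levels, each = n_dates),
    date = rep(grid_dates, p), stringsAsFactors = FALSE)
  key_obs <- paste(data$species, sprintf("%.6f", data$date))
  key_grid <- paste(df$species, sprintf("%.6f", df$date))
  idx <- match(key_grid, key_obs)
  df$y_raw <- data$estimate[idx]
  df$include <- ifelse(is.na(idx), FALSE, data$include[idx])
  df$observed <- !is.na(idx)
  df$year <- floor(df$date)

  U <- bspline_basis(df$date, spec)
  Q <- difference_matrix(spec$K, spec$r)
  Z1 <- mixed_model_design(U, Q)
  ds1 <- ncol(Z1)
  sp_f <- factor(df$species, levels = sp_levels)
  X <- outer(df$species, sp_levels, `==`) * 1
  colnames(X) <- sp_levels
  # block-diagonal per-species copy of Z1
  Z2 <- matrix(0, nrow(df), ds1 * p)
  for (j in seq_len(p)) {
    rows <- which(sp_f == sp_levels[j])
    Z2[rows, (j - 1L) * ds1 + seq_len(ds1)] <- Z1[rows, ]
  }
  if (fixed_species_slopes) {
    tc <- df$date - mean(spec$domain)
    Xs <- X * tc
    colnames(Xs) <- paste0(sp_levels, ":time")
    X <- cbind(X, Xs)
  }
  offset <- log(offs_mean[df$species])
  list(X = X, Z1 = Z1, Z2 = Z2, offset = as.numeric(offset),
       y = round(df$y_raw), y_raw = df$y_raw,
       observed = df$observed, include = df$include,
       species = df$species, date = df$date, year = df$year,
       species_levels = sp_levels, spec = spec,
       dims = list(n = nrow(df), p = p, ds1 = ds1, ds2 = ds1 * p,
                   n_fixed = ncol(X), random_total = ds1 + ds1 * p))
}

# One PQL outer loop over Henderson's mixed-model equations.
# Returns fit components; errors on non-convergence with the trace attached.
fit_pql <- function(md, control = sglmm_control()) {
  keep <- md$observed & md$include
  y <- md$y[keep]
  X <- md$X[keep, , drop = FALSE]
  Z1 <- md$Z1[keep, , drop = FALSE]
  Z2 <- md$Z2[keep, , drop = FALSE]
  off <- md$offset[keep]
  n <- length(y)
  fixed_vc <- !is.null(control$fix_vc)
  if (fixed_vc) {
    # an exactly-zero fixed variance removes its random-effect block
    if (control$fix_vc[1] == 0) Z1 <- Z1[, 0, drop = FALSE]
    if (control$fix_vc[2] == 0) Z2 <- Z2[, 0, drop = FALSE]
  }
  p <- ncol(X); ds1 <- ncol(Z1); ds2 <- ncol(Z2)
  M <- cbind(X, Z1, Z2)
  q_tot <- p + ds1 + ds2
  i_u1 <- p + seq_len(ds1)
  i_u2 <- p + ds1 + seq_len(ds2)

  # init: eta0 = log(y + 0.5); beta from least squares of (eta0 - offset)
  eta <- log(y + 0.5)
  beta <- stats::coef(stats::lm.fit(X, eta - off))
  beta[is.na(beta)] <- 0
  u <- rep(0, ds1 + ds2)
  s1 <- control$vc_init; s2 <- control$vc_init; k <- control$k_init
  if (fixed_vc) { s1 <- max(control$fix_vc[1], control$vc_min)
                  s2 <- max(control$fix_vc[2], control$vc_min) }
  eta <- drop(X %*% beta) + off

  trace <- data.frame(iter = integer(), sigma2_u1 = numeric(),
                      sigma2_u2 = numeric(), k = numeric(),
                      pql = numeric(), max_rel_change = numeric())
  pql_prev <- Inf
  monotone_viol <- 0L
  converged <- FALSE
  clamped <- c(sigma2_u1 = FALSE, sigma2_u2 = FALSE)

  for (it in seq_len(control$maxit)) {
    mu <- exp(eta)
    w <- mu / (1 + mu / k)
    e <- (eta - off) + (y - mu) / mu           # working variate (sans offset)
    sw <- sqrt(w)
    C <- crossprod(M * sw)
    pen <- c(rep(0, p), rep(1 / s1, ds1), rep(1 / s2, ds2))
    diag(C) <- diag(C) + pen
    rhs <- drop(crossprod(M, w * e))
    ch <- tryCatch(chol(C), error = function(err)
      stop("mixed-model equations not positive definite at iteration ", it))
    sol <- backsolve(ch, forwardsolve(t(ch), rhs))
    Cinv_diag <- diag(chol2inv(ch))

    beta_new <- sol[seq_len(p)]
    u_new <- sol[-seq_len(p)]
    u1 <- u_new[seq_len(ds1)]; u2 <- u_new[ds1 + seq_len(ds2)]

    # Schall-type REML fixed-point update for the two spline variances:
    # sigma_j^2 <- ||u_j||^2 / nu_j with nu_j the effective df of block j
    tr1 <- sum(Cinv_diag[i_u1]); tr2 <- sum(Cinv_diag[i_u2])
    nu1 <- if (ds1) ds1 - tr1 / s1 else 0
    nu2 <- if (ds2) ds2 - tr2 / s2 else 0
    if (fixed_vc) {
      s1_new <- s1; s2_new <- s2
    } else {
    s1_new <- if (nu1 > 1e-8) sum(u1^2) / nu1 else control$vc_min
    s2_new <- if (nu2 > 1e-8) sum(u2^2) / nu2 else control$vc_min
    # variances below vc_snap contribute nothing on the log-link scale but
    # decay only geometrically; snap them to the clamp so the fixed point
    # terminates
    if (s1_new < control$vc_snap) { s1_new <- control$vc_min
                                    clamped["sigma2_u1"] <- TRUE }
    if (s2_new < control$vc_snap) { s2_new <- control$vc_min
                                    clamped["sigma2_u2"] <- TRUE }
    }

    # Pearson moment-matching update of the NB shape on current residuals
    eta <- drop(M %*% sol) + off
    mu <- exp(eta)
    edf <- q_tot - tr1 / s1 - tr2 / s2
    edf <- min(max(edf, p), n - 1)
    k_new <- suppressWarnings(MASS::theta.mm(y, mu, dfr = n - edf))
    if (!is.finite(k_new) || k_new <= 0) k_new <- k
    k_new <- min(max(k_new, control$k_range[1]), control$k_range[2])

    # penalized quasi-deviance of the working model (monitored)
    res <- e - drop(M %*% sol)
    pql_obj <- sum(w * res^2) + sum(u1^2) / s1 + sum(u2^2) / s2
    if (pql_obj > pql_prev + 1e-8 * abs(pql_prev))
      monotone_viol <- monotone_viol + 1L
    pql_prev <- pql_obj

    old <- c(beta, u, s1, s2, k)
    new <- c(beta_new, u_new, s1_new, s2_new, k_new)
    rel <- max(abs(new - old) / (abs(old) + 1e-3))
    trace <- rbind(trace, data.frame(iter = it, sigma2_u1 = s1_new,
                                     sigma2_u2 = s2_new, k = k_new,
                                     pql = pql_obj, max_rel_change = rel))
    beta <- beta_new; u <- u_new; s1 <- s1_new; s2 <- s2_new; k <- k_new
    if (rel < control$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- simpleError(paste0("PQL did not converge in ", control$maxit,
                               " iterations (last max relative change ",
                               format(utils::tail(trace$max_rel_change, 1),
                                      digits = 4), ")"))
    cond$trace <- trace
    cond$last <- list(beta = beta, u = u, sigma2_u1 = s1, sigma2_u2 = s2,
                      k = k)
    stop(cond)
  }
  # joint precision at convergence -> covariance of (beta, u - u_hat)
  mu <- exp(drop(M %*% c(beta, u)) + off)
  w <- mu / (1 + mu / k)
  C <- crossprod(M * sqrt(w))
  diag(C) <- diag(C) + c(rep(0, p), rep(1 / s1, ds1), rep(1 / s2, ds2))
  cov <- chol2inv(chol(C))

  list(beta = stats::setNames(beta, colnames(X)),
       u1 = u[seq_len(ds1)], u2 = u[ds1 + seq_len(ds2)],
       sigma2_u1 = s1, sigma2_u2 = s2, k = k, cov = cov,
       iterations = nrow(trace), converged = converged, trace = trace,
       monotonicity_violations = monotone_viol, clamped = clamped,
       block_dims = c(p = p, ds1 = ds1, ds2 = ds2), n_fit = n)
}

#' Fit the multivariate semiparametric NB trend model
#'
#' Fits, by penalized quasi-likelihood, a negative-binomial mixed model for
#' the population estimates of several species observed on a shared
#' irregular survey calendar:
#' \deqn{\log \mu = X\beta + Z_1 u_1 + Z_2 u_2 + \mathrm{offset}}
#' with species intercepts as the only fixed effects (optionally plus
#' per-species linear time slopes), a P-spline time trend common to all
#' species (\code{u1}, i.i.d. \code{N(0, sigma2_u1)}), species-specific
#' P-spline trends (\code{u2}, i.i.d. \code{N(0, sigma2_u2)}), and the log
#' mean estimate of each species as offset.  Exactly three variance
#' components are estimated: the two spline variances and the NB shape
#' \code{k}.
#'
#' The response is the population estimate rounded to the nearest integer
#' (raw values are preserved in the fit).  Rows flagged \code{include =
#' FALSE} (e.g. outliers identified by graphical inspection) are kept for
#' plotting but excluded from fitting.
#'
#' @param formula \code{response ~ species}, naming the estimate column and
#'   the species column of \code{data}.
#' @param data data.frame with one row per species and survey date; must
#'   contain a \code{date} column (decimal years) or one named by
#'   \code{time}.
#' @param time name of the decimal-year time column (default \code{"date"}).
#' @param spline a \code{\link{spline_spec}} (default m = 20, d = 3, r = 3).
#' @param years calendar years the fit must cover (placeholder predictions
#'   are generated for years without surveys); default = observed span.
#' @param exclude optional data.frame of (species, date) rows to exclude
#'   from fitting (merged into the \code{include} flag).
#' @param fixed_species_slopes add per-species linear time fixed effects
#'   (the q = p "species x time" interaction columns).  Default \code{TRUE}:
#'   the P-spline random effects span only deviations from the penalty null
#'   space, so without these slope terms smooth log-linear trends are not
#'   representable and the REML variance updates collapse to a flat fit.
#'   \code{FALSE} gives the intercepts-only fixed design.
#' @param control a \code{\link{sglmm_control}}.
#' @return object of class \code{"sglmm"}: the fitted parameters
#'   (\code{beta}, \code{u1}, \code{u2}, \code{sigma2_u1}, \code{sigma2_u2},
#'   \code{k}), joint covariance, design bundle, and convergence trace.
#' @seealso \code{\link{predict.sglmm}}, \code{\link{summary.sglmm}}
#' @export
sglmm <- function(formula, data, time = "date", spline = spline_spec(),
                  years = NULL, exclude = NULL,
                  fixed_species_slopes = TRUE,
                  control = sglmm_control()) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  if (ncol(mf) != 2) stop("formula must be of the form estimate ~ species")
  if (!time %in% names(data)) stop("no time column '", time, "' in data")
  d <- data.frame(estimate = mf[[1]], species = as.character(mf[[2]]),
                  date = data[[time]], stringsAsFactors = FALSE)
  d$include <- if (!is.null(data$include)) data$include else TRUE
  if (!is.null(exclude)) {
    kx <- paste(exclude$species, round(exclude$date, 6))
    d$include <- d$include & !(paste(d$species, round(d$date, 6)) %in% kx)
  }
  md <- assemble_design(d, spec = spline, years = years,
                        fixed_species_slopes = fixed_species_slopes)
  fit <- fit_pql(md, control)
  # blocks removed by an exactly-zero fixed variance come back as zeros
  # (and zero covariance) so prediction over the full design still works
  full <- ncol(md$X) + ncol(md$Z1) + ncol(md$Z2)
  if (nrow(fit$cov) < full) {
    bd <- fit$block_dims
    kept <- c(seq_len(bd[["p"]]),
              if (bd[["ds1"]] > 0) ncol(md$X) + seq_len(ncol(md$Z1)),
              if (bd[["ds2"]] > 0)
                ncol(md$X) + ncol(md$Z1) + seq_len(ncol(md$Z2)))
    cov_full <- matrix(0, full, full)
    cov_full[kept, kept] <- fit$cov
    fit$cov <- cov_full
  }
  if (length(fit$u1) < ncol(md$Z1)) fit$u1 <- rep(0, ncol(md$Z1))
  if (length(fit$u2) < ncol(md$Z2)) fit$u2 <- rep(0, ncol(md$Z2))
  structure(c(fit, list(design = md, call = match.call(),
                        fixed_species_slopes = fixed_species_slopes)),
            class = "sglmm")
}

#' @export
print.sglmm <- function(x, ...) {
  d <- x$design$dims
  cat("Semiparametric NB mixed trend model (PQL)\n")
  cat("  ", d$p, " species, ", x$n_fit, " fitted observations (grid n = ",
      d$n, ")\n", sep = "")
  cat("  P-spline: ds1 = ", d$ds1, " common + ds2 = ", d$ds2,
      " species-specific random coefficients\n", sep = "")
  cat("  variance components: sigma2_u1 = ", format(x$sigma2_u1, digits = 4),
      ", sigma2_u2 = ", format(x$sigma2_u2, digits = 4),
      ", NB shape k = ", format(x$k, digits = 4), "\n", sep = "")
  cat("  converged in ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' @export
summary.sglmm <- function(object, ...) {
  p <- length(object$beta)
  se <- sqrt(diag(object$cov)[seq_len(p)])
  coefs <- cbind(Estimate = object$beta, `Std. Error` = se,
                 `z value` = object$beta / se)
  out <- list(coefficients = coefs,
              variance_components = c(sigma2_u1 = object$sigma2_u1,
                                      sigma2_u2 = object$sigma2_u2,
                                      k = object$k),
              iterations = object$iterations,
              monotonicity_violations = object$monotonicity_violations,
              dims = object$design$dims)
  class(out) <- "summary.sglmm"
  out
}

#' @export
print.summary.sglmm <- function(x, ...) {
  cat("Fixed effects (species intercepts on log scale):\n")
  stats::printCoefmat(x$coefficients)
  cat("\nVariance components:\n")
  print(x$variance_components)
  cat("\nPQL iterations:", x$iterations, "\n")
  invisible(x)
}

#' @export
coef.sglmm <- function(object, ...) object$beta

#' @export
fitted.sglmm <- function(object, ...) {
  md <- object$design
  eta <- sglmm_linpred(object, seq_len(md$dims$n))
  exp(eta)[md$observed]
}

#' @export
residuals.sglmm <- function(object,
                            type = c("pearson", "response", "deviance"),
                            ...) {
  type <- match.arg(type)
  md <- object$design
  keep <- md$observed & md$include
  mu <- exp(sglmm_linpred(object, which(keep)))
  y <- md$y[keep]
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu * (1 + mu / object$k)),
    deviance = {
      k <- object$k
      dv <- 2 * (ifelse(y > 0, y * log(y / mu), 0) -
                   (y + k) * log((y + k) / (mu + k)))
      sign(y - mu) * sqrt(pmax(dv, 0))
    })
}

# linear predictor (incl. offset) for given grid row indices
sglmm_linpred <- function(object, rows) {
  md <- object$design
  drop(md$X[rows, , drop = FALSE] %*% object$beta +
       md$Z1[rows, , drop = FALSE] %*% object$u1 +
       md$Z2[rows, , drop = FALSE] %*% object$u2) + md$offset[rows]
}

#' Predict yearly abundances with pointwise 95% bands
#'
#' Returns, for each species and calendar year, the model prediction
#' \code{exp(eta)} and the band \code{exp(eta +/- 1.96 SE(eta))}, where the
#' standard error comes from the joint PQL covariance of the intercepts and
#' spline coefficients.  Years with surveys are predicted at their actual
#' survey dates (possibly several rows per year); years without surveys at
#' mid-June.  Years outside the spline domain are refused.
#'
#' @param object a fitted \code{\link{sglmm}}.
#' @param years calendar years to predict (default: the fit's grid years).
#' @param level band coverage (default 0.95).
#' @param ... unused.
#' @return data.frame with \code{species}, \code{year}, \code{date},
#'   \code{fit}, \code{lwr}, \code{upr}, \code{observed}.
#' @export
predict.sglmm <- function(object, years = NULL, level = 0.95, ...) {
  md <- object$design
  if (is.null(years)) {
    rows <- seq_len(md$dims$n)
  } else {
    dom <- md$spec$domain
    bad <- years[years + 0.45 < dom[1] - 1 | years + 0.45 > dom[2] + 1]
    if (any(floor(dom[1]) > years) || any(years > floor(dom[2])))
      stop("cannot extrapolate: years ",
           paste(setdiff(years, floor(dom[1]):floor(dom[2])), collapse = ", "),
           " outside the spline domain [", dom[1], ", ", dom[2], "]")
    rows <- which(md$year %in% years)
  }
  M <- cbind(md$X[rows, , drop = FALSE], md$Z1[rows, , drop = FALSE],
             md$Z2[rows, , drop = FALSE])
  eta <- sglmm_linpred(object, rows)
  se <- sqrt(pmax(rowSums((M %*% object$cov) * M), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(species = md$species[rows], year = md$year[rows],
             date = md$date[rows], fit = exp(eta),
             lwr = exp(eta - zq * se), upr = exp(eta + zq * se),
             observed = md$observed[rows], stringsAsFactors = FALSE)
}

#' Simulate response vectors from a fitted trend model
#'
#' Draws negative-binomial replicates of the fitted observations (included
#' rows) from the fitted means and shape.
#'
#' @param object a fitted \code{\link{sglmm}}.
#' @param nsim number of replicate response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with one column per replicate, as
#'   \code{\link[stats]{simulate}} conventions.
#' @export
simulate.sglmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  md <- object$design
  keep <- md$observed & md$include
  mu <- exp(sglmm_linpred(object, which(keep)))
  out <- as.data.frame(
    replicate(nsim, stats::rnbinom(length(mu), size = object$k, mu = mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot fitted species trends
#'
#' Observed estimates (points; excluded rows hollow) with the fitted trend
#' line and 95% band per species, on a shared time axis.
#'
#' @param x a fitted \code{\link{sglmm}}.
#' @param species subset of species to draw (default all).
#' @param log_scale draw the response axis on the log scale.
#' @param ... passed to \code{plot}.
#' @export
plot.sglmm <- function(x, species = NULL, log_scale = FALSE, ...) {
  md <- x$design
  pr <- predict(x)
  spp <- if (is.null(species)) md$species_levels else species
  nsp <- length(spp)
  oldpar <- graphics::par(mfrow = c(ceiling(nsp / 2), min(nsp, 2)),
                          mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  for (sp in spp) {
    ps <- pr[pr$species == sp, ]
    obs <- md$observed & md$species == sp
    ylim <- range(c(ps$lwr, ps$upr, md$y_raw[obs]), na.rm = TRUE)
    plot(ps$date, ps$fit, type = "l", ylim = ylim,
         log = if (log_scale) "y" else "",
         xlab = "year", ylab = "population estimate", main = sp, ...)
    graphics::lines(ps$date, ps$lwr, lty = 2)
    graphics::lines(ps$date, ps$upr, lty = 2)
    graphics::points(md$date[obs], md$y_raw[obs],
                     pch = ifelse(md$include[obs], 16, 1))
  }
  invisible(x)
}
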