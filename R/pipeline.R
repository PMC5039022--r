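#' Default pipeline configuration
#'
#' Assembles a run configuration for \code{\link{run_pipeline}}: a synthetic
#' scenario (or paths to input CSVs), the spline settings, averaging
#' periods, biomass groups/weights and the selection criterion.
#'
#' @param scenario a \code{\link{scenario_config}} to simulate inputs from,
#'   or \code{NULL} when \code{paths} are given.
#' @param paths named list of input CSV paths (\code{units}, \code{design},
#'   and/or \code{estimates}, \code{covariates}, optional
#'   \code{exclusions}); ignored when \code{scenario} is given.
#' @param spline list with \code{m}, \code{d}, \code{r}.
#' @param periods list of \code{\link{period_spec}}s; the first is the
#'   baseline.
#' @param weights named unit-weight vector (kg/animal).
#' @param groups named list of species vectors for biomass groups.
#' @param selection_criterion information criterion for forward selection.
#' @param baseline_1978 use the 1978-1980 baseline variant instead of
#'   1977-1980.
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(scenario = scenario_config(),
                       paths = NULL,
                       spline = list(m = 20, d = 3, r = 3),
                       periods = NULL,
                       weights = default_unit_weights(),
                       groups = list(
                         livestock = c("shoats", "cattle", "camel", "donkey"),
                         wildlife = c("wildebeest", "giraffe", "zebra",
                                      "elephant", "buffalo", "ostrich",
                                      "impala", "hartebeest", "topi", "oryx",
                                      "eland", "waterbuck",
                                      "thomsons_gazelle", "grants_gazelle",
                                      "gerenuk", "lesser_kudu",
                                      "grevys_zebra", "warthog")),
                       selection_criterion = "AICc",
                       baseline_1978 = FALSE) {
  if (is.null(scenario) && is.null(paths))
    stop("either a scenario or input paths must be given")
  if (is.null(periods)) {
    yrs <- if (!is.null(scenario)) scenario$years else NULL
    b0 <- if (baseline_1978) 1978 else 1977
    periods <- list(period_spec(paste0(b0, "-1980"), b0, 1980),
                    period_spec("1994-1997", 1994, 1997),
                    period_spec("2011-2013", 2011, 2013))
    if (!is.null(yrs))
      periods <- Filter(function(p) p$start >= min(yrs) && p$end <= max(yrs),
                        periods)
  }
  structure(list(scenario = scenario, paths = paths, spline = spline,
                 periods = periods, weights = weights, groups = groups,
                 selection_criterion = selection_criterion),
            class = "run_config")
}

stage <- function(name, verbose, expr) {
  t0 <- proc.time()[3]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  if (verbose)
    message(sprintf("[%s] done in %.1fs", name, proc.time()[3] - t0))
  res
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> survey estimation -> per-county trend
#' model -> aggregation (annual series, regional sums, period changes,
#' biomass) -> covariate analyses, writing every stage's table as CSV to
#' \code{outdir} together with a JSON manifest (record counts, seeds,
#' input hashes, warnings).  Reruns with the same configuration produce
#' byte-identical CSVs.
#'
#' @param config a \code{\link{run_config}}.
#' @param outdir output directory (created if needed).
#' @param verbose log per-stage timing.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config, outdir, verbose = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  warn_log <- character(0)
  log_warn <- function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  inputs <- stage("inputs", verbose, {
    if (!is.null(config$scenario)) {
      indir <- file.path(outdir, "inputs")
      write_scenario(config$scenario, indir)
      list(units = file.path(indir, "units.csv"),
           design = file.path(indir, "design.csv"),
           covariates = file.path(indir, "covariates.csv"),
           truth = file.path(indir, "truth.csv"))
    } else {
      for (p in unlist(config$paths))
        if (!file.exists(p)) stop("input file not found: ", p)
      config$paths
    }
  })

  estimates <- stage("estimate", verbose, {
    if (!is.null(inputs$units)) {
      units <- utils::read.csv(inputs$units)
      design <- utils::read.csv(inputs$design)
      est <- withCallingHandlers(estimate_all(units, design),
                                 warning = log_warn)
    } else {
      est <- utils::read.csv(inputs$estimates)
    }
    if (!is.null(inputs$exclusions)) {
      ex <- utils::read.csv(inputs$exclusions)
      kx <- paste(ex$county, ex$species, round(ex$date, 6))
      est$include <- !(paste(est$county, est$species,
                             round(est$date, 6)) %in% kx)
    } else est$include <- TRUE
    utils::write.csv(est, file.path(outdir, "estimates.csv"),
                     row.names = FALSE)
    est
  })

  preds <- stage("trend", verbose, {
    sp <- config$spline
    out <- list(); diags <- list()
    for (co in sort(unique(estimates$county))) {
      sub <- estimates[estimates$county == co, , drop = FALSE]
      fit <- withCallingHandlers(
        sglmm(estimate ~ species, data = sub,
              spline = spline_spec(sp$m, sp$d, sp$r)),
        warning = log_warn)
      pr <- predict(fit)
      pr$county <- co
      out[[co]] <- pr[, c("county", "species", "year", "date", "fit",
                          "lwr", "upr", "observed")]
      diags[[co]] <- list(sigma2_u1 = fit$sigma2_u1,
                          sigma2_u2 = fit$sigma2_u2, k = fit$k,
                          iterations = fit$iterations)
    }
    pr <- do.call(rbind, c(out, make.row.names = FALSE))
    utils::write.csv(pr, file.path(outdir, "trend_predictions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(diags, file.path(outdir, "fit_diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
    pr
  })

  agg <- stage("aggregate", verbose, {
    annual <- annualize(preds, value = "fit")
    nat <- national_sum(annual, value = "fit")
    utils::write.csv(nat, file.path(outdir, "national_trends.csv"),
                     row.names = FALSE)
    base <- config$periods[[1]]
    chg <- list()
    for (p in config$periods[-1]) {
      ma <- period_mean(nat, base, value = "fit")
      mb <- period_mean(nat, p, value = "fit")
      m <- merge(ma, mb, by = "species", suffixes = c("_base", "_cmp"))
      chg[[p$label]] <- data.frame(
        species = m$species, baseline = base$label, period = p$label,
        mean_base = m$fit_base, mean_cmp = m$fit_cmp,
        pct_change = round(percent_change(m$fit_base, m$fit_cmp), 1),
        stringsAsFactors = FALSE)
    }
    chg <- do.call(rbind, c(chg, make.row.names = FALSE))
    utils::write.csv(chg, file.path(outdir, "period_changes.csv"),
                     row.names = FALSE)
    groups <- lapply(config$groups, intersect, unique(annual$species))
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    bio <- biomass_rollup(annual, config$weights, groups,
                          config$periods, value = "fit")
    utils::write.csv(bio$group_biomass,
                     file.path(outdir, "biomass_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(bio$county_shares,
                     file.path(outdir, "county_shares.csv"),
                     row.names = FALSE)
    list(annual = annual, national = nat, changes = chg, biomass = bio)
  })

  stage("covariates", verbose, {
    if (is.null(inputs$covariates)) return(NULL)
    cov <- utils::read.csv(inputs$covariates)
    cli <- list()
    for (co in sort(unique(cov$county))) {
      sub <- cov[cov$county == co, ]
      for (v in c("annual_rainfall", "tmax_mean", "tmin_mean")) {
        tt <- climate_trend_test(sub$year, sub[[v]])
        cli[[paste(co, v)]] <- data.frame(
          county = co, variable = v, slope = tt$slope, se = tt$se,
          p_value = tt$p_value, n = tt$n, stringsAsFactors = FALSE)
      }
    }
    utils::write.csv(do.call(rbind, c(cli, make.row.names = FALSE)),
                     file.path(outdir, "climate_trends.csv"),
                     row.names = FALSE)
    # species density vs covariates at county-year granularity
    dat <- merge(agg$annual, cov, by.x = c("county", "year"),
                 by.y = c("county", "year"))
    uni <- list(); seltr <- list()
    covars <- c("human_density", "pct_protected", "annual_rainfall",
                "tmax_mean", "tmin_mean")
    for (sp in sort(unique(dat$species))) {
      d <- dat[dat$species == sp, ]
      for (v in covars) {
        f <- tryCatch(fit_density_curve(d$fit, d[[v]], d$county_area_km2),
                      error = function(e) NULL)
        if (is.null(f)) next
        pk <- peak_location(f)
        uni[[paste(sp, v)]] <- data.frame(
          species = sp, covariate = v, form = f$form,
          intercept = f$coefficients[["intercept"]],
          beta = f$coefficients[["beta"]],
          gamma = f$coefficients[["gamma"]], AICc = f$AICc,
          peak = pk$peak, stringsAsFactors = FALSE)
      }
      fs <- tryCatch(
        forward_select(d$fit, d[, covars], d$county_area_km2,
                       criterion = config$selection_criterion),
        error = function(e) NULL)
      if (!is.null(fs)) {
        tr <- fs$trace
        tr$species <- sp
        seltr[[sp]] <- tr
      }
    }
    utils::write.csv(do.call(rbind, c(uni, make.row.names = FALSE)),
                     file.path(outdir, "univariate_fits.csv"),
                     row.names = FALSE)
    if (length(seltr))
      utils::write.csv(do.call(rbind, c(seltr, make.row.names = FALSE)),
                       file.path(outdir, "selection_trace.csv"),
                       row.names = FALSE)
    NULL
  })

  manifest <- list(
    package = "srftrends",
    version = as.character(utils::packageVersion("srftrends")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = if (!is.null(config$scenario)) config$scenario$seed else NA,
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    tables = {
      csvs <- list.files(outdir, pattern = "\\.csv$", full.names = TRUE)
      stats::setNames(lapply(csvs, function(f)
        nrow(utils::read.csv(f))), basename(csvs))
    },
    warnings = warn_log)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Summarize a completed pipeline run
#'
#' Reads the tables written by \code{\link{run_pipeline}} and returns the
#' headline summaries: per-species percent change between the baseline and
#' each later period, and biomass group totals, shares and ratios per
#' period.  A pure function of the run directory contents.
#'
#' @param run_dir directory written by \code{\link{run_pipeline}}.
#' @return list with \code{changes}, \code{biomass}, \code{ratios},
#'   \code{county_shares}, printed compactly.
#' @export
report_run <- function(run_dir) {
  need <- c("period_changes.csv", "biomass_summary.csv", "county_shares.csv")
  for (f in need)
    if (!file.exists(file.path(run_dir, f)))
      stop("incomplete run: missing ", f)
  out <- list(
    changes = utils::read.csv(file.path(run_dir, "period_changes.csv")),
    biomass = utils::read.csv(file.path(run_dir, "biomass_summary.csv")),
    county_shares = utils::read.csv(file.path(run_dir, "county_shares.csv")))
  class(out) <- "srf_report"
  out
}

#' @export
print.srf_report <- function(x, ...) {
  cat("Percent change in regional population size by species:\n")
  print(x$changes, row.names = FALSE)
  cat("\nBiomass by group and period:\n")
  print(x$biomass, row.names = FALSE)
  invisible(x)
}
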