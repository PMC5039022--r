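#' Synthetic SRF survey scenario configuration
#'
#' Defines the generating model for synthetic aerial strip-transect
#' monitoring data: the survey design (5 x 5 km sampling units, a sampling
#' fraction near the historical 5.7% coverage, irregular survey years with
#' gaps), negative-binomial unit counts, species with flat, exponentially
#' declining/growing or logistically increasing density trajectories, and
#' county covariate series (exponential human population growth, linear
#' warming, noisy rainfall with a weak trend).
#'
#' Species are given as a named list; each element is a list with fields
#' \code{density} (animals/km2 at the start year), \code{trend} (one of
#' \code{"flat"}, \code{"exponential"}, \code{"logistic"}), \code{rate}
#' (per-year rate; negative for exponential decline) and, for logistic
#' trends, \code{ceiling} (asymptote as a multiple of the initial density).
#'
#' All randomness flows from \code{seed} through named substreams, so each
#' stage (surveys, estimate-level series, covariates) can be regenerated
#' independently and reproducibly.
#'
#' @param n_counties number of counties.
#' @param county_areas census-zone areas in km2, length \code{n_counties}.
#' @param species named list of species trajectories (see Details).
#' @param nb_shape_k negative-binomial shape (overdispersion) parameter > 0.
#' @param years full monitoring year range.
#' @param survey_years subset of \code{years} in which surveys happen.
#' @param unit_area_km2 nominal sampling-unit area (default 25 = 5 x 5 km).
#' @param unit_area_cv coefficient of variation of realised unit areas
#'   (transects of unequal length); 0 gives equal-area units.
#' @param sampling_fraction proportion of units sampled, in (0, 1].
#' @param census_years human-census anchor years.
#' @param human_growth_rate mean exponential growth rate of county human
#'   populations (per year).
#' @param human_pop0 mean county human population at the first census.
#' @param rain_mean,rain_trend,rain_sd annual rainfall mean (mm), linear
#'   trend (mm/yr) and noise SD.
#' @param tmax0,tmin0 mean annual max/min temperature at the start (deg C).
#' @param warming linear warming trend (deg C / yr) for both series.
#' @param temp_sd temperature noise SD (deg C).
#' @param seed integer master seed.
#' @return object of class \code{"scenario_config"}.
#' @export
scenario_config <- function(n_counties = 3,
                            county_areas = c(17000, 9000, 25000)[seq_len(n_counties)],
                            species = default_species(),
                            nb_shape_k = 2,
                            years = 1977:2016,
                            survey_years = setdiff(years,
                              years[c(3, 7, 8, 12, 16, 17, 21, 25, 26,
                                      30, 34, 38)]),
                            unit_area_km2 = 25,
                            unit_area_cv = 0.1,
                            sampling_fraction = 0.057,
                            census_years = c(1962, 1969, 1979, 1989, 1999, 2009),
                            human_growth_rate = 0.0335,
                            human_pop0 = 120000,
                            rain_mean = 600, rain_trend = -1, rain_sd = 90,
                            tmax0 = 28, tmin0 = 16,
                            warming = 0.02, temp_sd = 0.3,
                            seed = 1L) {
  if (length(county_areas) != n_counties)
    stop("need one county area per county")
  if (any(county_areas <= 0)) stop("county areas must be positive")
  if (!(sampling_fraction > 0 && sampling_fraction <= 1))
    stop("sampling_fraction must be in (0, 1]")
  if (nb_shape_k <= 0) stop("nb_shape_k must be > 0")
  if (unit_area_km2 <= 0) stop("unit_area_km2 must be positive")
  if (!length(years)) stop("empty year range")
  if (!length(survey_years) || !all(survey_years %in% years))
    stop("survey_years must be a nonempty subset of years")
  for (nm in names(species)) {
    sp <- species[[nm]]
    if (is.null(sp$density) || sp$density < 0)
      stop("species '", nm, "': density must be >= 0")
    if (!sp$trend %in% c("flat", "exponential", "logistic"))
      stop("species '", nm, "': unknown trend type '", sp$trend, "'")
  }
  n_units <- floor(county_areas / unit_area_km2)
  n_sample <- pmax(2L, round(sampling_fraction * n_units))
  if (any(n_sample > n_units))
    stop("design error: sampling_fraction implies more sampled units than ",
         "exist in a county")
  structure(list(
    n_counties = n_counties,
    counties = paste0("county", seq_len(n_counties)),
    county_areas = county_areas,
    species = species, nb_shape_k = nb_shape_k,
    years = years, survey_years = sort(survey_years),
    unit_area_km2 = unit_area_km2, unit_area_cv = unit_area_cv,
    sampling_fraction = sampling_fraction,
    total_units_N = n_units, units_per_survey = n_sample,
    census_years = census_years,
    human_growth_rate = human_growth_rate, human_pop0 = human_pop0,
    rain_mean = rain_mean, rain_trend = rain_trend, rain_sd = rain_sd,
    tmax0 = tmax0, tmin0 = tmin0, warming = warming, temp_sd = temp_sd,
    seed = as.integer(seed)), class = "scenario_config")
}

#' Default species set for the synthetic scenario
#'
#' A small community emulating the dominant observed patterns: rising shoats
#' (logistic), slowly declining cattle, two wildlife species in steep
#' exponential decline (2.88%/yr, about 68% over 39 years) and one flat.
#' @return named list of species trajectory definitions.
#' @export
default_species <- function() {
  list(
    shoats     = list(density = 6.0, trend = "logistic",   rate = 0.15,
                      ceiling = 1.9),
    cattle     = list(density = 8.0, trend = "exponential", rate = -0.00726),
    wildebeest = list(density = 1.5, trend = "exponential", rate = -0.0288),
    giraffe    = list(density = 0.6, trend = "exponential", rate = -0.0288),
    zebra      = list(density = 1.0, trend = "flat",        rate = 0)
  )
}

# Deterministic per-stream seed below 2^31, derived from master seed + name.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 97)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# True per-km2 density of one species at decimal year t.
true_density <- function(sp, t, t0) {
  dt <- t - t0
  switch(sp$trend,
    flat = rep(sp$density, length(t)),
    exponential = sp$density * exp(sp$rate * dt),
    logistic = {
      cmax <- sp$ceiling * sp$density
      cmax / (1 + (sp$ceiling - 1) * exp(-sp$rate * dt))
    })
}

#' True abundance ledger for a scenario
#'
#' @param config a \code{\link{scenario_config}}.
#' @return \code{data.frame} with columns \code{county}, \code{species},
#'   \code{year}, \code{abundance} (true totals, every year in the range).
#' @export
simulate_truth <- function(config) {
  t0 <- min(config$years)
  grid <- expand.grid(year = config$years,
                      species = names(config$species),
                      county = config$counties,
                      stringsAsFactors = FALSE)
  grid$abundance <- NA_real_
  for (ci in seq_len(config$n_counties)) {
    for (sp in names(config$species)) {
      idx <- grid$county == config$counties[ci] & grid$species == sp
      grid$abundance[idx] <-
        true_density(config$species[[sp]], grid$year[idx], t0) *
        config$county_areas[ci]
    }
  }
  grid[, c("county", "species", "year", "abundance")]
}

#' Simulate one aerial survey (unit-level counts)
#'
#' Draws the realised areas of the sampled units (gamma-distributed around
#' the nominal unit area with the configured coefficient of variation) and
#' negative-binomial per-unit counts with mean = true density x unit area
#' and shape \code{nb_shape_k}, for every species.  Design constants
#' (zone area Z, total units N) are returned alongside.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param county county name or index.
#' @param year survey year (must be in \code{config$survey_years}).
#' @return list of class \code{"survey_sample"} with elements \code{units}
#'   (long data.frame: county, date, unit_id, unit_area_km2, species, count)
#'   and \code{design} (one-row data.frame: county, date, zone_area_km2,
#'   total_units_N).
#' @export
simulate_survey <- function(config, county, year) {
  ci <- if (is.numeric(county)) as.integer(county)
        else match(county, config$counties)
  if (is.na(ci) || ci < 1 || ci > config$n_counties)
    stop("unknown county: ", county)
  if (!year %in% config$survey_years)
    stop("year ", year, " is not a survey year in this scenario")
  cname <- config$counties[ci]
  Z <- config$county_areas[ci]
  N <- config$total_units_N[ci]
  n <- config$units_per_survey[ci]
  if (n > N) stop("design error: n > N")
  set.seed(substream_seed(config$seed,
                          paste0("survey:", cname, ":", year)))
  cv <- config$unit_area_cv
  z <- if (cv > 0)
    stats::rgamma(n, shape = 1 / cv^2, scale = config$unit_area_km2 * cv^2)
  else rep(config$unit_area_km2, n)
  date <- year + 0.45  # mid-June convention
  t0 <- min(config$years)
  sp_names <- names(config$species)
  counts <- lapply(sp_names, function(sp) {
    d <- true_density(config$species[[sp]], date, t0)
    if (d == 0) integer(n)
    else stats::rnbinom(n, size = config$nb_shape_k, mu = d * z)
  })
  units <- data.frame(
    county = cname, date = date, unit_id = rep(seq_len(n), length(sp_names)),
    unit_area_km2 = rep(z, length(sp_names)),
    species = rep(sp_names, each = n),
    count = unlist(counts), stringsAsFactors = FALSE)
  design <- data.frame(county = cname, date = date, zone_area_km2 = Z,
                       total_units_N = N, stringsAsFactors = FALSE)
  structure(list(units = units, design = design), class = "survey_sample")
}

#' Simulate all surveys of a scenario
#'
#' @param config a \code{\link{scenario_config}}.
#' @return list with \code{units} and \code{design} data.frames stacking
#'   every (county, survey year) combination.
#' @export
simulate_surveys <- function(config) {
  us <- list(); ds <- list()
  for (cname in config$counties)
    for (yr in config$survey_years) {
      s <- simulate_survey(config, cname, yr)
      us[[length(us) + 1L]] <- s$units
      ds[[length(ds) + 1L]] <- s$design
    }
  list(units = do.call(rbind, us), design = do.call(rbind, ds))
}

#' Simulate estimate-level survey series
#'
#' Draws one negative-binomial "population estimate" per county, species and
#' survey year with mean equal to the true abundance — the granularity at
#' which the trend model operates.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return \code{data.frame} with columns \code{county}, \code{species},
#'   \code{date} (decimal year), \code{estimate}, \code{se} (set to
#'   \code{NA}).
#' @export
simulate_estimates <- function(config) {
  truth <- simulate_truth(config)
  sub <- truth[truth$year %in% config$survey_years, ]
  set.seed(substream_seed(config$seed, "estimates"))
  sub <- sub[order(sub$county, sub$species, sub$year), ]
  est <- stats::rnbinom(nrow(sub), size = config$nb_shape_k,
                        mu = sub$abundance)
  data.frame(county = sub$county, species = sub$species,
             date = sub$year + 0.45, estimate = as.numeric(est),
             se = NA_real_, stringsAsFactors = FALSE)
}

#' Simulate county covariate tables
#'
#' Human population grows exponentially through the census anchor years with
#' county-specific rates; values between anchors follow the exact
#' exponential interpolation used by \code{\link{interpolate_census}}.
#' Rainfall is mean + linear trend + Gaussian noise (floored at 1 mm);
#' temperatures are linear warming trends + noise.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return \code{data.frame}: \code{county}, \code{year},
#'   \code{human_pop}, \code{human_density}, \code{annual_rainfall},
#'   \code{tmax_mean}, \code{tmin_mean}, \code{pct_protected},
#'   \code{county_area_km2}.
#' @export
simulate_covariates <- function(config) {
  yrs <- seq(min(c(config$years, config$census_years)),
             max(config$years))
  out <- list()
  for (ci in seq_len(config$n_counties)) {
    cname <- config$counties[ci]
    set.seed(substream_seed(config$seed, paste0("covariates:", cname)))
    # per-county growth rate jitter around the configured mean
    g <- config$human_growth_rate * exp(stats::rnorm(1, 0, 0.15))
    anchors <- config$census_years
    p0 <- config$human_pop0 * exp(stats::rnorm(1, 0, 0.3))
    pops <- p0 * exp(g * (anchors - anchors[1]))
    hum <- vapply(yrs, function(t) {
      if (t <= anchors[1]) pops[1] * exp(g * (t - anchors[1]))
      else if (t >= anchors[length(anchors)])
        pops[length(pops)] * exp(g * (t - anchors[length(anchors)]))
      else {
        i <- findInterval(t, anchors)
        interpolate_census(pops[i], anchors[i], pops[i + 1], anchors[i + 1], t)
      }
    }, numeric(1))
    rain <- pmax(config$rain_mean + config$rain_trend * (yrs - yrs[1]) +
                   (if (config$rain_sd > 0)
                      stats::rnorm(length(yrs), 0, config$rain_sd) else 0), 1)
    tmax <- config$tmax0 + stats::rnorm(1, 0, 1) +
      config$warming * (yrs - yrs[1]) +
      (if (config$temp_sd > 0) stats::rnorm(length(yrs), 0, config$temp_sd) else 0)
    tmin <- config$tmin0 + stats::rnorm(1, 0, 1) +
      config$warming * (yrs - yrs[1]) +
      (if (config$temp_sd > 0) stats::rnorm(length(yrs), 0, config$temp_sd) else 0)
    prot <- stats::runif(1, 0, 30)
    out[[ci]] <- data.frame(
      county = cname, year = yrs, human_pop = hum,
      human_density = hum / config$county_areas[ci],
      annual_rainfall = rain, tmax_mean = tmax, tmin_mean = tmin,
      pct_protected = prot, county_area_km2 = config$county_areas[ci],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' True percent change between two periods
#'
#' Computes, from the truth ledger, the exact percent change in the
#' cross-county total abundance of each species between two periods, with
#' the same period-mean-then-percent-change arithmetic as the analysis
#' pipeline (\code{\link{period_mean}} / \code{\link{percent_change}}).
#'
#' @param truth output of \code{\link{simulate_truth}}.
#' @param periodA,periodB integer year vectors (baseline and comparison).
#' @return \code{data.frame} with \code{species}, \code{meanA}, \code{meanB},
#'   \code{pct_change}.
#' @export
truth_summary <- function(truth, periodA, periodB) {
  if (!length(periodA) || !length(periodB)) stop("empty period")
  if (!all(periodA %in% truth$year) || !all(periodB %in% truth$year))
    stop("period outside the simulated year range")
  nat <- stats::aggregate(abundance ~ species + year, data = truth, FUN = sum)
  per_mean <- function(period) {
    sub <- nat[nat$year %in% period, ]
    stats::aggregate(abundance ~ species, data = sub, FUN = mean)
  }
  a <- per_mean(periodA); b <- per_mean(periodB)
  m <- merge(a, b, by = "species", suffixes = c("A", "B"))
  data.frame(species = m$species, meanA = m$abundanceA, meanB = m$abundanceB,
             pct_change = mapply(percent_change, m$abundanceA, m$abundanceB),
             stringsAsFactors = FALSE)
}

#' Write scenario tables to CSV
#'
#' Writes \code{units.csv}, \code{design.csv}, \code{estimates.csv},
#' \code{covariates.csv} and \code{truth.csv} under \code{dir}.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_scenario <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  svy <- simulate_surveys(config)
  paths <- c(units = file.path(dir, "units.csv"),
             design = file.path(dir, "design.csv"),
             estimates = file.path(dir, "estimates.csv"),
             covariates = file.path(dir, "covariates.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(svy$units, paths["units"], row.names = FALSE)
  utils::write.csv(svy$design, paths["design"], row.names = FALSE)
  utils::write.csv(simulate_estimates(config), paths["estimates"],
                   row.names = FALSE)
  utils::write.csv(simulate_covariates(config), paths["covariates"],
                   row.names = FALSE)
  utils::write.csv(simulate_truth(config), paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Read a scenario configuration from a YAML file
#'
#' Top-level YAML keys map to \code{\link{scenario_config}} arguments;
#' \code{species} is a named mapping with \code{density}, \code{trend},
#' \code{rate} and optional \code{ceiling} per species.
#'
#' @param path YAML file path.
#' @return a \code{\link{scenario_config}}.
#' @export
scenario_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown scenario fields: ", paste(unknown, collapse = ", "))
  do.call(scenario_config, cfg)
}
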