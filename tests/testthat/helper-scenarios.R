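# Shared simulation settings used across test files.

# four species in a common exponential decline (about 68% over 39 years)
decline_species <- function(rate = -0.0288) {
  list(a = list(density = 2,   trend = "exponential", rate = rate),
       b = list(density = 1,   trend = "exponential", rate = rate),
       c = list(density = 0.5, trend = "exponential", rate = rate),
       d = list(density = 4,   trend = "exponential", rate = rate))
}

decline_config <- function(seed, nb_shape_k = 2, ...) {
  scenario_config(n_counties = 1, county_areas = 17000,
                  species = decline_species(), nb_shape_k = nb_shape_k,
                  seed = seed, ...)
}

# period-mean percent change per species from a prediction table
fitted_pct_change <- function(pred, periodA, periodB, value = "fit") {
  pred$county <- "one"
  ann <- annualize(pred, value = value)
  by_sp <- split(ann, ann$species)
  vapply(by_sp, function(d)
    percent_change(mean(d[[value]][d$year %in% periodA]),
                   mean(d[[value]][d$year %in% periodB])), numeric(1))
}

# Narok-like survey calendar: 34 surveys over 1977-2014 leaving 11 calendar
# years unsurveyed (38 years total, 27 surveyed, 7 with two surveys)
narok_calendar <- function() {
  all_years <- 1977:2014
  missing <- c(1979, 1983, 1986, 1990, 1993, 1997, 2001, 2004, 2008, 2011,
               2013)
  surveyed <- setdiff(all_years, missing)          # 27 years
  dates <- surveyed + 0.2
  twice <- surveyed[1:7]
  sort(c(dates, twice + 0.7))                      # 34 distinct dates
}
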