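#' Averaging period specification
#'
#' A labelled inclusive year range used to average predicted population
#' series before computing changes, with optional per-county end-year
#' overrides (some counties' last surveys extend a period by a year or
#' three).
#'
#' @param label period label, e.g. \code{"2011-2013"}.
#' @param start,end first and last calendar year (inclusive).
#' @param end_overrides optional named integer vector of per-county end
#'   years, e.g. \code{c(Narok = 2016)}.
#' @return object of class \code{"period_spec"}.
#' @export
period_spec <- function(label, start, end, end_overrides = NULL) {
  if (start > end) stop("period start after end")
  if (!is.null(end_overrides)) {
    if (is.null(names(end_overrides)) || any(names(end_overrides) == ""))
      stop("end_overrides must be a named vector")
    if (any(end_overrides < start))
      stop("end override before period start")
  }
  structure(list(label = label, start = start, end = end,
                 end_overrides = end_overrides), class = "period_spec")
}

period_years <- function(period, county = NULL) {
  end <- period$end
  if (!is.null(county) && !is.null(period$end_overrides) &&
      county %in% names(period$end_overrides))
    end <- period$end_overrides[[county]]
  seq(period$start, end)
}

#' Average multiple surveys within each calendar year
#'
#' Collapses a series of estimates or predictions to one value per
#' (county, species, year) by arithmetic mean.  Rows flagged as excluded
#' (\code{include = FALSE}) are dropped before averaging; single-survey
#' years pass through unchanged.
#'
#' @param x data.frame with columns \code{county}, \code{species},
#'   \code{date} (decimal year) or \code{year}, a value column, and
#'   optionally \code{include} (logical).
#' @param value name of the value column (default \code{"estimate"}).
#' @return data.frame with \code{county}, \code{species}, \code{year} and
#'   the averaged value column.
#' @export
annualize <- function(x, value = "estimate") {
  if (!nrow(x)) stop("empty input")
  if (!value %in% names(x)) stop("no column '", value, "'")
  if ("include" %in% names(x)) x <- x[x$include, , drop = FALSE]
  yr <- if ("year" %in% names(x)) x$year else floor(x$date)
  agg <- stats::aggregate(x[[value]],
                          by = list(county = x$county, species = x$species,
                                    year = yr),
                          FUN = mean)
  names(agg)[4] <- value
  agg[order(agg$county, agg$species, agg$year), ]
}

#' Sum annual county series into regional ("national") totals
#'
#' Every county must contribute a value for every species-year present —
#' gaps are an error (unsurveyed years must first be filled by model
#' predictions), never a silent zero.
#'
#' @param annual data.frame from \code{\link{annualize}} (columns
#'   \code{county}, \code{species}, \code{year}, value).
#' @param value value column name.
#' @return data.frame with \code{species}, \code{year}, summed value.
#' @export
national_sum <- function(annual, value = "estimate") {
  counties <- unique(annual$county)
  key <- paste(annual$species, annual$year)
  tab <- table(key)
  bad <- names(tab)[tab != length(counties)]
  if (length(bad)) {
    k <- strsplit(bad[1], " ")[[1]]
    have <- annual$county[key == bad[1]]
    stop("missing county contribution for species '", k[1], "', year ",
         k[2], " (absent: ",
         paste(setdiff(counties, have), collapse = ", "), ")")
  }
  agg <- stats::aggregate(annual[[value]],
                          by = list(species = annual$species,
                                    year = annual$year), FUN = sum)
  names(agg)[3] <- value
  agg[order(agg$species, agg$year), ]
}

#' Period mean abundance per species
#'
#' Averages an annual series over the years of a period.  If the series is
#' county-level, per-county end-year overrides are honoured before any
#' cross-county summation by the caller.
#'
#' @param annual data.frame with \code{species}, \code{year}, value and
#'   optionally \code{county}.
#' @param period a \code{\link{period_spec}}.
#' @param value value column name.
#' @return data.frame with \code{species} (and \code{county} if present) and
#'   the period-mean value.
#' @export
period_mean <- function(annual, period, value = "estimate") {
  has_county <- "county" %in% names(annual)
  if (has_county) {
    keep <- mapply(function(co, yr) yr %in% period_years(period, co),
                   annual$county, annual$year)
  } else {
    keep <- annual$year %in% period_years(period)
  }
  sub <- annual[keep, , drop = FALSE]
  if (!nrow(sub)) stop("period '", period$label,
                       "' does not overlap the series")
  by <- if (has_county) list(county = sub$county, species = sub$species)
        else list(species = sub$species)
  agg <- stats::aggregate(sub[[value]], by = by, FUN = mean)
  names(agg)[ncol(agg)] <- value
  agg
}

#' Percent change between two period means
#'
#' Baseline-referenced signed percent change \code{100 * (b - a) / a}.
#'
#' @param a baseline period mean (> 0).
#' @param b comparison period mean.
#' @return signed percent (numeric; report at one decimal, compute on
#'   unrounded values).
#' @examples
#' percent_change(4101984.8, 3068000.7) # -25.2
#' @export
percent_change <- function(a, b) {
  if (any(a <= 0)) stop("percent change undefined for baseline mean <= 0")
  100 * (b - a) / a
}

#' Linear annualized rate of change
#'
#' @param total_percent total percent change over the span.
#' @param span_years span in years (> 0).
#' @return percent per year, \code{total_percent / span_years}.
#' @examples
#' annualized_rate(68.1, 40) # 1.7 per year
#' @export
annualized_rate <- function(total_percent, span_years) {
  if (any(span_years <= 0)) stop("span must be positive")
  total_percent / span_years
}

#' Illustrative species unit weights
#'
#' Per-animal unit weights (kg) used to convert counts to biomass.  These
#' defaults are illustrative values typical of the literature and are NOT a
#' canonical table; analyses of real data should supply their own weights.
#'
#' @return named numeric vector, kg per animal.
#' @export
default_unit_weights <- function() {
  c(cattle = 180, shoats = 18, camel = 300, donkey = 120,
    zebra = 200, wildebeest = 123, giraffe = 750, elephant = 1725,
    buffalo = 450, ostrich = 114, impala = 40, hartebeest = 125,
    topi = 100, oryx = 150, eland = 340, waterbuck = 160,
    thomsons_gazelle = 15, grants_gazelle = 40, gerenuk = 30,
    lesser_kudu = 70, grevys_zebra = 350, warthog = 45)
}

#' Biomass aggregation, group ratios, shares and county distributions
#'
#' Converts annual species counts to biomass (count x unit weight), sums
#' within groups (e.g. wildlife vs livestock) over the years of each period
#' (period mean of annual group biomass), and reports per period: group
#' biomass, between-group ratios, group shares of the total, and the
#' proportional distribution of each species' biomass across counties
#' (shares summing to 100% per species and period).
#'
#' @param annual county-level annual series (\code{county}, \code{species},
#'   \code{year}, value column).
#' @param weights named vector of unit weights (kg/animal) covering every
#'   species present, e.g. \code{\link{default_unit_weights}()}.
#' @param groups named list of species character vectors, e.g.
#'   \code{list(wildlife = ..., livestock = ...)}; species in no group are an
#'   error unless listed in \code{exclude}.
#' @param periods list of \code{\link{period_spec}} objects.
#' @param value value column name.
#' @param exclude species to drop explicitly.
#' @return list with data.frames \code{group_biomass} (period, group,
#'   biomass_kg, share_pct), \code{ratios} (period, numerator, denominator,
#'   ratio) and \code{county_shares} (period, species, county, share_pct).
#' @export
biomass_rollup <- function(annual, weights, groups, periods,
                           value = "estimate", exclude = character(0)) {
  annual <- annual[!annual$species %in% exclude, , drop = FALSE]
  spp <- unique(annual$species)
  miss <- setdiff(spp, names(weights))
  if (length(miss))
    stop("no unit weight for species: ", paste(miss, collapse = ", "))
  ungrouped <- setdiff(spp, unlist(groups))
  if (length(ungrouped))
    stop("species in no group (add to a group or 'exclude'): ",
         paste(ungrouped, collapse = ", "))
  annual$biomass_kg <- annual[[value]] * weights[annual$species]

  gb <- list(); ra <- list(); cs <- list()
  gnames <- names(groups)
  for (p in periods) {
    pm <- period_mean(annual, p, value = "biomass_kg")
    # group totals: sum period-mean county biomass over species and counties
    tot <- vapply(gnames, function(g)
      sum(pm$biomass_kg[pm$species %in% groups[[g]]]), numeric(1))
    gb[[p$label]] <- data.frame(period = p$label, group = gnames,
                                biomass_kg = as.numeric(tot),
                                share_pct = 100 * as.numeric(tot) / sum(tot),
                                stringsAsFactors = FALSE)
    if (length(gnames) >= 2) {
      cmb <- utils::combn(gnames, 2)
      ra[[p$label]] <- data.frame(
        period = p$label, numerator = cmb[1, ], denominator = cmb[2, ],
        ratio = tot[cmb[1, ]] / tot[cmb[2, ]], stringsAsFactors = FALSE)
    }
    sp_tot <- stats::aggregate(biomass_kg ~ species, data = pm, FUN = sum)
    m <- merge(pm, sp_tot, by = "species", suffixes = c("", "_total"))
    cs[[p$label]] <- data.frame(
      period = p$label, species = m$species, county = m$county,
      share_pct = 100 * m$biomass_kg / m$biomass_kg_total,
      stringsAsFactors = FALSE)
  }
  list(group_biomass = do.call(rbind, c(gb, make.row.names = FALSE)),
       ratios = do.call(rbind, c(ra, make.row.names = FALSE)),
       county_shares = do.call(rbind, c(cs, make.row.names = FALSE)))
}
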