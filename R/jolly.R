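#' Jolly's Method 2 population estimate for transects of unequal length
#'
#' Design-based ratio estimator for aerial strip-transect (SRF) survey
#' samples.  With \code{y} the animals counted in each sampled unit, \code{z}
#' the unit areas, \code{Z} the census-zone area and \code{N} the number of
#' sampling units in the zone, the density is \code{R = sum(y)/sum(z)}, the
#' population total \code{Y = Z * R}, and
#' \deqn{Var(\hat Y) = \frac{N(N-n)}{n}\,(s_y^2 - 2\hat R s_{zy} +
#'   \hat R^2 s_z^2)}
#' with sample variances/covariance on \code{n - 1} denominators and
#' \code{SE = sqrt(max(Var, 0))}.  The finite-population factor makes the
#' SE exactly 0 for a complete census (\code{n = N}), and the variance
#' vanishes when counts are exactly proportional to areas.
#'
#' A negative variance (possible in finite samples) is clamped to zero with
#' a warning.  With a single sampled unit the estimate is returned but the
#' SE is \code{NA} (variance undefined), with a warning.
#'
#' @param y nonnegative counts per sampled unit (one species).
#' @param z positive sampled-unit areas, same length as \code{y}.
#' @param Z census-zone area (same units as \code{z}).
#' @param N total number of sampling units in the zone, \code{N >= n}.
#' @param county,species,date optional identifiers carried through.
#' @return a one-row \code{data.frame} with columns \code{county},
#'   \code{species}, \code{date}, \code{estimate}, \code{se},
#'   \code{density}, \code{n}.
#' @examples
#' jolly_method2(y = c(2, 4, 6, 8), z = rep(5, 4), Z = 100, N = 20)
#' @export
jolly_method2 <- function(y, z, Z, N, county = NA_character_,
                          species = NA_character_, date = NA) {
  n <- length(y)
  stopifnot(length(z) == n, n >= 1, length(Z) == 1, length(N) == 1)
  if (any(y < 0)) stop("negative counts")
  if (any(z <= 0)) stop("unit areas must be positive")
  if (N < n) stop("total units N = ", N, " smaller than sample size n = ", n)
  if (sum(z) > Z + 1e-8 * Z)
    stop("sampled area exceeds zone area Z")
  sz <- sum(z)
  if (sz == 0) stop("total sampled area is zero; density undefined")
  R <- sum(y) / sz
  Yhat <- Z * R
  if (n == 1) {
    warning("n = 1: variance of the Jolly estimate is undefined")
    se <- NA_real_
  } else {
    s_y2 <- stats::var(y)
    s_z2 <- stats::var(z)
    s_zy <- stats::cov(z, y)
    v <- N * (N - n) / n * (s_y2 - 2 * R * s_zy + R^2 * s_z2)
    if (v < 0) {
      warning("negative variance estimate (", format(v), ") clamped to 0")
      v <- 0
    }
    se <- sqrt(v)
  }
  data.frame(county = county, species = species, date = date,
             estimate = Yhat, se = se, density = R, n = n,
             stringsAsFactors = FALSE)
}

#' Jolly estimates for every survey in a unit-level count table
#'
#' Applies \code{\link{jolly_method2}} to each (county, date, species) cell
#' of a unit-level table, sharing the design constants of the survey.
#' Species not listed for a survey are omitted (they are unknown, not zero);
#' a species listed with all-zero counts yields estimate 0 with SE 0.
#'
#' @param units \code{data.frame} with columns \code{county}, \code{date},
#'   \code{unit_id}, \code{unit_area_km2}, \code{species}, \code{count}.
#' @param design \code{data.frame} with columns \code{county}, \code{date},
#'   \code{zone_area_km2}, \code{total_units_N}; one row per survey.
#' @return \code{data.frame} of estimates, one row per (county, species,
#'   date), columns \code{county}, \code{species}, \code{date},
#'   \code{estimate}, \code{se}, \code{density}, \code{n}.
#' @export
estimate_all <- function(units, design) {
  need <- c("county", "date", "unit_id", "unit_area_km2", "species", "count")
  if (!all(need %in% names(units)))
    stop("units table must have columns: ", paste(need, collapse = ", "))
  needd <- c("county", "date", "zone_area_km2", "total_units_N")
  if (!all(needd %in% names(design)))
    stop("design table must have columns: ", paste(needd, collapse = ", "))
  ukey <- paste(units$county, units$date, sep = "\r")
  dkey <- paste(design$county, design$date, sep = "\r")
  miss <- setdiff(unique(ukey), dkey)
  if (length(miss))
    stop("no design constants for survey: ",
         paste(gsub("\r", " / ", miss), collapse = "; "))
  out <- vector("list", 0L)
  for (k in unique(ukey)) {
    svy <- units[ukey == k, , drop = FALSE]
    des <- design[match(k, dkey), ]
    for (sp in unique(svy$species)) {
      rows <- svy[svy$species == sp, , drop = FALSE]
      out[[length(out) + 1L]] <- jolly_method2(
        y = rows$count, z = rows$unit_area_km2,
        Z = des$zone_area_km2, N = des$total_units_N,
        county = rows$county[1], species = sp, date = rows$date[1])
    }
  }
  if (!length(out))
    return(data.frame(county = character(), species = character(),
                      date = character(), estimate = numeric(),
                      se = numeric(), density = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
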