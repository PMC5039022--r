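#' P-spline configuration
#'
#' Defines the penalized B-spline (P-spline) smoother used for the temporal
#' trend terms of the semiparametric mixed model: a B-spline basis of degree
#' \code{d} with \code{m} equally spaced interior knots on a time domain, and
#' an \code{r}-th order difference penalty on adjacent spline coefficients.
#'
#' The basis has \code{K = m + d + 1} columns.  After the mixed-model
#' reparameterization (see \code{\link{mixed_model_design}}) the penalized
#' coefficients become \code{ds1 = K - r} i.i.d. random effects, so \code{r}
#' must be smaller than \code{K}.
#'
#' @param m number of equally spaced interior knots (default 20).
#' @param d B-spline degree (default 3, cubic). Must be >= 1.
#' @param r order of the difference penalty (default 3).
#' @param domain numeric length-2 vector, start and end of the time domain in
#'   decimal years. May be \code{NULL} at construction and supplied later.
#' @return an object of class \code{"spline_spec"} with elements \code{m},
#'   \code{d}, \code{r}, \code{K}, \code{ds1} and \code{domain}.
#' @examples
#' sp <- spline_spec(m = 20, d = 3, r = 3)
#' sp$K   # 24
#' sp$ds1 # 21
#' @export
spline_spec <- function(m = 20, d = 3, r = 3, domain = NULL) {
  stopifnot(length(m) == 1, length(d) == 1, length(r) == 1)
  m <- as.integer(m); d <- as.integer(d); r <- as.integer(r)
  if (m < 0) stop("'m' (interior knot count) must be >= 0")
  if (d < 1) stop("'d' (B-spline degree) must be >= 1")
  if (r < 1) stop("'r' (difference order) must be >= 1")
  K <- m + d + 1L
  if (K <= r) stop("difference order r = ", r, " requires K = m + d + 1 > r")
  if (!is.null(domain)) {
    stopifnot(is.numeric(domain), length(domain) == 2)
    if (domain[1] >= domain[2]) stop("degenerate domain: start >= end")
  }
  structure(list(m = m, d = d, r = r, K = K, ds1 = K - r, domain = domain),
            class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  cat("P-spline: ", x$m, " interior knots, degree ", x$d,
      ", difference order ", x$r, "\n", sep = "")
  cat("  basis columns K = ", x$K, ", penalized dimension ds1 = ", x$ds1,
      "\n", sep = "")
  if (!is.null(x$domain))
    cat("  domain [", x$domain[1], ", ", x$domain[2], "] decimal years\n",
        sep = "")
  invisible(x)
}

#' Knot vector for a P-spline basis
#'
#' Places \code{m} equally spaced interior knots strictly inside the domain,
#' anchored by \code{d} extra knots stacked on the starting date and
#' \code{max(1, d)} extra knots stacked on the ending date (both boundary
#' dates are themselves knots), i.e. the open knot vector with boundary
#' multiplicity \code{d + 1} that yields exactly \code{K = m + d + 1} basis
#' functions forming a partition of unity on the domain.
#'
#' @param spec a \code{\link{spline_spec}} whose \code{domain} is set.
#' @param domain optional length-2 numeric overriding \code{spec$domain}.
#' @return numeric knot vector of length \code{m + 2 * (d + 1)}, suitable for
#'   \code{splines::splineDesign} with \code{ord = d + 1}.
#' @export
build_knots <- function(spec, domain = spec$domain) {
  if (is.null(domain)) stop("spline domain is not set")
  stopifnot(is.numeric(domain), length(domain) == 2)
  a <- domain[1]; b <- domain[2]
  if (a >= b) stop("degenerate domain: start >= end")
  interior <- if (spec$m > 0)
    seq(a, b, length.out = spec$m + 2L)[-c(1L, spec$m + 2L)] else numeric(0)
  c(rep(a, spec$d + 1L), interior, rep(b, max(1L, spec$d) + 1L))
}

#' Evaluate the B-spline basis matrix
#'
#' Rows are evaluation points (decimal years), columns the \code{K} basis
#' functions.  Points must lie within the closed domain.
#'
#' @param x numeric vector of evaluation points.
#' @param spec a \code{\link{spline_spec}} with domain set.
#' @param domain optional domain override.
#' @return numeric matrix, \code{length(x)} by \code{spec$K}.
#' @export
bspline_basis <- function(x, spec, domain = spec$domain) {
  knots <- build_knots(spec, domain)
  a <- domain[1]; b <- domain[2]
  if (any(x < a - 1e-9) || any(x > b + 1e-9))
    stop("evaluation points outside the spline domain [", a, ", ", b, "]")
  x <- pmin(pmax(x, a), b)
  splines::splineDesign(knots, x, ord = spec$d + 1L, outer.ok = FALSE)
}

#' r-th order difference-penalty matrix
#'
#' The \code{(K - r) x K} matrix whose rows hold the r-th order
#' finite-difference stencil (binomial coefficients with alternating signs),
#' so that \code{Q \%*\% b} is the vector of r-th differences of the spline
#' coefficients \code{b}.
#'
#' @param K number of spline coefficients.
#' @param r difference order, \code{1 <= r < K}.
#' @return numeric matrix of dimension \code{(K - r) x K}.
#' @examples
#' difference_matrix(3, 1) # rows (-1, 1, 0) and (0, -1, 1)
#' @export
difference_matrix <- function(K, r) {
  K <- as.integer(K); r <- as.integer(r)
  if (r < 1) stop("'r' must be >= 1")
  if (K <= r) stop("need K > r, got K = ", K, ", r = ", r)
  diff(diag(K), differences = r)
}

#' Mixed-model reparameterization of a penalized B-spline
#'
#' Transforms the B-spline evaluation matrix \code{U} so that the r-th order
#' difference penalty on the spline coefficients becomes an i.i.d. ridge
#' penalty on new coefficients: \code{Z = U G Q'} with \code{G} the
#' Moore-Penrose inverse of \code{Q'Q}.  For the full-row-rank difference
#' matrix this equals \code{U Q'(QQ')^{-1}}, the standard P-spline
#' random-effect design with \code{K - r} columns.
#'
#' @param U basis matrix from \code{\link{bspline_basis}} (n x K).
#' @param Q penalty matrix from \code{\link{difference_matrix}} ((K-r) x K).
#' @return numeric matrix n x (K - r).
#' @export
mixed_model_design <- function(U, Q) {
  if (ncol(U) != ncol(Q))
    stop("nonconformable: ncol(U) = ", ncol(U), " but ncol(Q) = ", ncol(Q))
  Z <- U %*% MASS::ginv(crossprod(Q)) %*% t(Q)
  rk <- qr(Z)$rank
  if (rk < min(dim(Z)))
    warning("random-effect design is rank deficient (rank ", rk, " < ",
            min(dim(Z)), ")")
  Z
}

#' Basis of the penalty null space
#'
#' Columns span the polynomials of degree r-1 in the spline-coefficient
#' index, i.e. the directions the r-th order difference penalty leaves
#' unpenalized.  Used by the penalized-fit / mixed-model equivalence checks.
#'
#' @param K number of spline coefficients.
#' @param r difference order.
#' @return K x r matrix.
#' @keywords internal
penalty_nullspace <- function(K, r) {
  outer(seq_len(K), seq_len(r) - 1L, `^`)
}
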