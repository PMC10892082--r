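#' Bond-angle density of a d-dimensional fixed-bond random walk
#'
#' For two independent uniformly-random bond directions in d dimensions the
#' bending angle theta between them has density proportional to
#' sin^(d-2)(theta) on (0, 180): uniform in the plane (d = 2),
#' sin(theta) in 3D.  The normalization constant is computed by numerical
#' quadrature (analytically it is a Beta function; quadrature keeps the
#' code honest for any real d >= 2).
#'
#' @param theta angle(s) in degrees, in (0, 180).
#' @param d spatial dimension, >= 2.
#' @return normalized density per degree.
#' @export
p_theta <- function(theta, d) {
  if (d < 2) stop("dimension must be >= 2")
  if (any(theta <= 0 | theta >= 180)) stop("theta must lie in (0, 180)")
  k <- stats::integrate(function(t) sin(t * pi / 180)^(d - 2),
                        0, 180, rel.tol = 1e-10)$value
  sin(theta * pi / 180)^(d - 2) / k
}

#' CDF of the bond-bending angle of a d-dimensional random walk
#'
#' Integral of [p_theta()]; closed form in d = 2 (linear) and d = 3
#' ((1 - cos theta)/2), quadrature otherwise.  Used as the reference
#' distribution in sampling tests.
#'
#' @inheritParams p_theta
#' @return cumulative probability P(angle <= theta).
#' @export
p_theta_cdf <- function(theta, d) {
  if (d < 2) stop("dimension must be >= 2")
  th <- pmin(pmax(theta, 0), 180)
  if (d == 2) return(th / 180)
  if (d == 3) return((1 - cos(th * pi / 180)) / 2)
  k <- stats::integrate(function(t) sin(t * pi / 180)^(d - 2),
                        0, 180, rel.tol = 1e-10)$value
  vapply(th, function(u)
    stats::integrate(function(t) sin(t * pi / 180)^(d - 2) / k,
                     0, u, rel.tol = 1e-10)$value, numeric(1))
}

#' Density of the inverse circumradius of a two-step random walk
#'
#' Changing variables from the bending angle theta (density
#' sin^(d-2) theta) through R = b / (2 cos(theta/2)) gives the density of
#' X = 1/R on (0, 2/b):
#' P(X) proportional to (X b)^(d-2) * (1 - (X b / 2)^2)^((d-3)/2).
#' The normalization constant is computed by quadrature.  In d = 3 the
#' bracket exponent vanishes and the density is exactly linear,
#' P(X) = X b^2 / 2.
#'
#' @param X inverse radius (1/angstrom), in (0, 2/b).
#' @param d spatial dimension >= 2.
#' @param b bond length (angstrom).
#' @return normalized density.
#' @export
pdf_inverse_radius <- function(X, d, b) {
  if (d < 2) stop("dimension must be >= 2")
  if (b <= 0) stop("bond length must be positive")
  if (any(X <= 0 | X >= 2 / b)) stop("X must lie in (0, 2/b)")
  f <- function(x) (x * b)^(d - 2) * (1 - (x * b / 2)^2)^((d - 3) / 2)
  k <- stats::integrate(f, 0, 2 / b, rel.tol = 1e-10)$value
  f(X) / k
}

#' Asymptotic CDF power-law exponent for the inverse radius
#'
#' The cumulative distribution of X = 1/R for triplets of a d-dimensional
#' fixed-bond walk behaves as X^(d-1) in the large-radius limit X*b << 1:
#' the density goes as X^(d-2), and integrating adds one power.
#'
#' @param d spatial dimension >= 2.
#' @return the exponent d - 1.
#' @export
cdf_exponent <- function(d) {
  if (d < 2) stop("dimension must be >= 2")
  d - 1
}

#' Closed-form inverse-radius CDF for a 3D two-step walk
#'
#' In three dimensions the change of variables gives the exact cumulative
#' distribution P(1/r <= X) = (X b / 2)^2 on [0, 2/b] -- not merely
#' asymptotically, since the d = 3 density is exactly linear in X.
#'
#' @param X inverse radius (1/angstrom), in [0, 2/b].
#' @param b bond length (angstrom).
#' @return cumulative probability.
#' @export
cdf_inverse_radius_closed_form <- function(X, b) {
  if (b <= 0) stop("bond length must be positive")
  if (any(X < 0 | X > 2 / b)) stop("X must lie in [0, 2/b]")
  (X * b / 2)^2
}

#' Reference constants of the walk-angle theory
#'
#' Normalization constants of [p_theta()] and [pdf_inverse_radius()] and the
#' CDF exponents for a few dimensions, as a data.frame (exported to CSV by
#' the pipeline for documentation).
#'
#' @param dims integer vector of dimensions.
#' @param b bond length (angstrom).
#' @return data.frame with one row per dimension.
#' @export
theory_constants <- function(dims = 2:5, b = 3.81) {
  data.frame(
    d = dims,
    cdf_exponent = vapply(dims, cdf_exponent, numeric(1)),
    p_theta_norm = vapply(dims, function(d)
      stats::integrate(function(t) sin(t * pi / 180)^(d - 2),
                       0, 180, rel.tol = 1e-10)$value, numeric(1)),
    pdf_x_norm = vapply(dims, function(d)
      stats::integrate(function(x)
        (x * b)^(d - 2) * (1 - (x * b / 2)^2)^((d - 3) / 2),
        0, 2 / b, rel.tol = 1e-10)$value, numeric(1)))
}
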