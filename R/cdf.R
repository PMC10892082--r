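#' Inverse radii for batches of point triplets and quartets
#'
#' Vectorized versions of [circumradius_triplet()] and
#' [circumsphere_radius_quartet()] for large samples: each row of `pts`
#' holds the concatenated coordinates of one triplet (9 numbers) or one
#' quartet (12 numbers).  Degenerate sets (collinear triplets, coplanar
#' quartets) get X = 0, the infinite-radius convention.
#'
#' @param pts numeric matrix, one point set per row.
#' @param collinear_tol,det_tol degeneracy thresholds as in the scalar
#'   functions.
#' @return numeric vector of X = 1/R values (1/angstrom).
#' @export
triplet_inverse_radii <- function(pts, collinear_tol = 1e-12) {
  stopifnot(ncol(pts) == 9L)
  p1 <- pts[, 1:3, drop = FALSE]
  p2 <- pts[, 4:6, drop = FALSE]
  p3 <- pts[, 7:9, drop = FALSE]
  a <- sqrt(rowSums((p2 - p3)^2))
  b <- sqrt(rowSums((p1 - p3)^2))
  cc <- sqrt(rowSums((p1 - p2)^2))
  cr <- rowcross(p2 - p1, p3 - p1)
  area <- 0.5 * sqrt(rowSums(cr * cr))
  x <- 4 * area / (a * b * cc)
  x[x < collinear_tol] <- 0
  x
}

#' @rdname triplet_inverse_radii
#' @export
quartet_inverse_radii <- function(pts, det_tol = 1e-12) {
  stopifnot(ncol(pts) == 12L)
  r <- cpp_quartet_radii(pts, det_tol)
  ifelse(is.finite(r), 1 / r, 0)
}

#' Inverse radii of all consecutive triplets / quartets along a chain
#'
#' @param conf a `conformation`.
#' @return numeric vector of X = 1/R over consecutive triplets (length
#'   n - 2) or quartets (length n - 3).
#' @export
chain_triplet_inverse_radii <- function(conf) {
  x <- conf$coords
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 monomers")
  triplet_inverse_radii(cbind(x[1:(n - 2), , drop = FALSE],
                              x[2:(n - 1), , drop = FALSE],
                              x[3:n, , drop = FALSE]))
}

#' @rdname chain_triplet_inverse_radii
#' @export
chain_quartet_inverse_radii <- function(conf) {
  x <- conf$coords
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 monomers")
  quartet_inverse_radii(cbind(x[1:(n - 3), , drop = FALSE],
                              x[2:(n - 2), , drop = FALSE],
                              x[3:(n - 1), , drop = FALSE],
                              x[4:n, , drop = FALSE]))
}

#' Empirical cumulative distribution of inverse radii
#'
#' Builds the empirical CDF of X = 1/R from a sample of inverse radii.
#' Samples with infinite radius enter at X = 0, so they contribute to the
#' cumulative probability everywhere without distorting the positive-X
#' power law.
#'
#' @param x numeric vector of X = 1/R values, or a list of `radius_sample`
#'   objects.
#' @param b optional bond length (angstrom) recorded with the table so fit
#'   windows can be specified in the dimensionless variable X*b.
#' @return a `cdf_table`: list with sorted unique `x`, cumulative
#'   probabilities `p` = P(1/r <= x), the sample count `n` and `b`.
#' @export
inverse_radius_cdf <- function(x, b = NULL) {
  if (is.list(x)) x <- vapply(x, function(s) s$X, numeric(1))
  x <- as.numeric(x)
  if (!length(x)) stop("empty sample")
  if (anyNA(x) || any(x < 0)) stop("inverse radii must be >= 0")
  n <- length(x)
  xs <- sort(x)
  ux <- unique(xs)
  p <- cumsum(tabulate(match(xs, ux), length(ux))) / n
  structure(list(x = ux, p = p, n = n, b = b), class = "cdf_table")
}

#' @export
print.cdf_table <- function(x, ...) {
  cat("<cdf_table> ", x$n, " samples, X range [",
      format(min(x$x)), ", ", format(max(x$x)), "]",
      if (!is.null(x$b)) paste0(", b = ", format(x$b)), "\n", sep = "")
  invisible(x)
}

#' Evaluate a cdf_table at arbitrary points
#'
#' @param cdf a `cdf_table`.
#' @param at numeric vector of X values.
#' @return cumulative probabilities P(1/r <= at).
#' @export
cdf_at <- function(cdf, at) {
  stopifnot(inherits(cdf, "cdf_table"))
  idx <- findInterval(at, cdf$x)
  ifelse(idx == 0, 0, cdf$p[pmax(idx, 1)])
}

#' Power-law exponent of a CDF by log-log least squares
#'
#' Fits the slope of log10 P versus log10 X over a window of X, the
#' standard way to read off the power-law exponent of the inverse-radius
#' CDF in its asymptotic (large-radius, X*b << 1) regime.  The default
#' window is X*b in [0.05, 0.5], using the bond length stored in the table;
#' the CDF is evaluated on a log-spaced grid inside the window and the
#' slope comes from an ordinary least-squares line.
#'
#' @param cdf a `cdf_table`.
#' @param fit_window length-2 numeric, window in X (1/angstrom).  Overrides
#'   `xb_window`.
#' @param xb_window length-2 numeric, window in the dimensionless X*b
#'   (requires `b` in the table or as argument).
#' @param b bond length override for `xb_window`.
#' @param n_grid number of log-spaced evaluation points.
#' @return fitted slope (dimensionless exponent).
#' @export
fit_loglog_slope <- function(cdf, fit_window = NULL,
                             xb_window = c(0.05, 0.5), b = NULL,
                             n_grid = 200L) {
  stopifnot(inherits(cdf, "cdf_table"))
  if (is.null(fit_window)) {
    if (is.null(b)) b <- cdf$b
    if (is.null(b))
      stop("no bond length available: give `fit_window` or `b`")
    fit_window <- xb_window / b
  }
  stopifnot(length(fit_window) == 2L, all(fit_window > 0),
            fit_window[1] < fit_window[2])
  inside <- cdf$x > 0 & cdf$x >= fit_window[1] & cdf$x <= fit_window[2]
  if (sum(inside) < 10L)
    stop("fewer than 10 positive CDF points inside the fit window")
  grid <- exp(seq(log(fit_window[1]), log(fit_window[2]),
                  length.out = n_grid))
  p <- cdf_at(cdf, grid)
  keep <- p > 0
  if (sum(keep) < 10L) stop("CDF is zero over most of the fit window")
  fit <- stats::lm(log10(p[keep]) ~ log10(grid[keep]))
  unname(stats::coef(fit)[2])
}

#' Write a cdf_table to CSV
#'
#' Columns: `x` (1/angstrom) and `p` = P(1/r <= x).
#'
#' @param cdf a `cdf_table`.
#' @param path output path.
#' @export
write_cdf_csv <- function(cdf, path) {
  utils::write.csv(data.frame(x = cdf$x, p = cdf$p), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
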