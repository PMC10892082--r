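#' Histogram mode of a sample
#'
#' Mode as the center of the fullest fixed-width histogram bin.  Bins are
#' anchored at zero, so a bin width of 0.02 angstrom gives centers at
#' 0.01, 0.03, ...; this resolves modes to the 0.01-angstrom level while
#' averaging over sampling noise.
#'
#' @param x numeric sample (non-finite values dropped).
#' @param bin_width histogram bin width.
#' @return the center of the most populated bin.
#' @export
hist_mode <- function(x, bin_width) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values to histogram")
  idx <- floor(x / bin_width)
  tab <- table(idx)
  k <- as.numeric(names(tab)[which.max(tab)])
  (k + 0.5) * bin_width
}

#' Characteristic-scale mode on the inverse scale
#'
#' Mode estimator used for the characteristic length scales: the sample is
#' histogrammed as X = 1/length (the inverse-radius variable the package's
#' distribution machinery works in), the bin counts are smoothed with a
#' loess fit (span 0.25, degree 2) over the occupied bins, and the argmax
#' bin center is inverted back to a length.  Smoothing stabilizes the
#' argmax on broad, flat distributions (the tangent chain at infinite
#' temperature) where a raw fullest-bin estimate jitters by several bins;
#' sharp distributions occupy few bins and fall back to the raw argmax,
#' which the smoothing could only blur.
#'
#' @param lengths positive lengths (angstrom); `Inf` allowed (enters at
#'   X = 0).
#' @param xbin histogram bin width on the inverse scale (1/angstrom).
#' @param min_bins fewer occupied bins than this triggers the raw-argmax
#'   fallback.
#' @param span loess span for the smoothing fit.
#' @return the modal length (angstrom).
#' @export
inverse_scale_mode <- function(lengths, xbin, min_bins = 15L, span = 0.25) {
  x <- 1 / lengths[is.finite(lengths) & lengths > 0]
  x <- c(x, rep(0, sum(is.infinite(lengths))))
  if (!length(x)) stop("no usable lengths")
  h <- graphics::hist(x, breaks = seq(0, max(x) + xbin, by = xbin),
                      plot = FALSE)
  keep <- h$counts > 0
  raw <- h$mids[keep][which.max(h$counts[keep])]
  if (sum(keep) < min_bins) return(1 / raw)
  fit <- stats::loess(counts ~ mids,
                      data = data.frame(mids = h$mids[keep],
                                        counts = h$counts[keep]),
                      span = span, degree = 2)
  sm <- h$mids[keep][which.max(stats::predict(fit))]
  1 / sm
}

#' Local radii of every interior triplet of a set of conformations
#'
#' R = b / (2 cos(theta/2)) at each interior vertex.  End monomers have no
#' interior triplet and are excluded.  With `pure_class` set, only
#' triplets whose three monomers all carry that label are kept.
#'
#' @param confs a `conformation` or list of them.
#' @param pure_class optional class label for pure-triplet filtering.
#' @return numeric vector of local radii (angstrom; `Inf` for straight
#'   triplets).
#' @export
local_radii <- function(confs, pure_class = NULL) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  unlist(lapply(confs, function(cf) {
    th <- chain_thetas(cf$coords)
    r <- local_radius_from_theta(th, cf$b)
    if (!is.null(pure_class)) {
      lab <- cf$labels
      if (is.null(lab)) stop("conformation has no labels for class filter")
      n <- nrow(cf$coords)
      pure <- lab[1:(n - 2)] == pure_class &
        lab[2:(n - 1)] == pure_class & lab[3:n] == pure_class
      r <- r[pure]
    }
    r
  }), use.names = FALSE)
}

#' Nearest non-local contact distances over a set of conformations
#'
#' @inheritParams local_radii
#' @param min_sep minimum sequence separation (default 3).
#' @param class_filter optional label: keep only monomers i of that class.
#' @return numeric vector of contact distances (angstrom).
#' @export
contact_distances <- function(confs, min_sep = 3L, class_filter = NULL) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  unlist(lapply(confs, function(cf) {
    rec <- nearest_nonlocal_contact(cf, min_sep = min_sep)
    d <- rec$distance
    if (!is.null(class_filter)) {
      if (is.null(cf$labels)) stop("conformation has no labels for class filter")
      d <- d[cf$labels[rec$i] == class_filter]
    }
    d
  }), use.names = FALSE)
}

#' Characteristic local and non-local length scales
#'
#' The two scales that summarize a chain ensemble: the histogram mode of
#' the local radius of curvature R = b / (2 cos(theta/2)) over interior
#' triplets (bin width 0.02 angstrom), and the histogram mode of the
#' distance to the nearest non-local contact, |i - j| >= 3 (bin width
#' 0.04 angstrom).  With `class_filter`, local radii use only pure
#' triplets (all three monomers in the class) and contact distances only
#' monomers of the class.
#'
#' @param confs a `conformation` or list of them.
#' @param class_filter optional class label.
#' @param estimator `"inverse"` (default) estimates the modes on the
#'   inverse scale via [inverse_scale_mode()] with bins `local_xbin` and
#'   `nonlocal_xbin`; `"direct"` uses fullest-bin modes of the lengths
#'   themselves with bins `local_bin` and `nonlocal_bin`.
#' @param local_bin,nonlocal_bin direct-scale histogram bin widths
#'   (angstrom).
#' @param local_xbin,nonlocal_xbin inverse-scale bin widths (1/angstrom);
#'   0.004 matches the 0.02-angstrom direct resolution at the steric floor.
#' @param min_sep minimum contact separation.
#' @return list with `local` and `nonlocal` modes (angstrom) and the
#'   underlying sample sizes.
#' @export
length_scale_modes <- function(confs, class_filter = NULL,
                               estimator = c("inverse", "direct"),
                               local_bin = 0.02, nonlocal_bin = 0.04,
                               local_xbin = 0.004, nonlocal_xbin = 0.001,
                               min_sep = 3L) {
  estimator <- match.arg(estimator)
  r <- local_radii(confs, pure_class = class_filter)
  d <- contact_distances(confs, min_sep = min_sep,
                         class_filter = class_filter)
  if (!length(r) || !length(d))
    stop("no data for class ",
         if (is.null(class_filter)) "<all>" else class_filter)
  list(local = scale_mode(r, estimator, local_bin, local_xbin),
       nonlocal = scale_mode(d, estimator, nonlocal_bin, nonlocal_xbin),
       n_local = sum(is.finite(r)), n_nonlocal = length(d))
}

scale_mode <- function(v, estimator, bin, xbin) {
  if (estimator == "direct") hist_mode(v, bin)
  else inverse_scale_mode(v, xbin)
}

#' Length scales straight from an MC snapshot array
#'
#' Fast path for the samplers' 3 x n x k snapshot arrays: local radii via
#' the vectorized angle kernel, contact distances via the compiled
#' nearest-contact scan.
#'
#' @param snaps 3 x n x k array.
#' @param b bond length (angstrom).
#' @inheritParams length_scale_modes
#' @return as [length_scale_modes()].
#' @export
snapshot_length_scales <- function(snaps, b,
                                   estimator = c("inverse", "direct"),
                                   local_bin = 0.02, nonlocal_bin = 0.04,
                                   local_xbin = 0.004,
                                   nonlocal_xbin = 0.001, min_sep = 3L) {
  stopifnot(length(dim(snaps)) == 3L, dim(snaps)[1] == 3L)
  estimator <- match.arg(estimator)
  n <- dim(snaps)[2]
  k <- dim(snaps)[3]
  r <- snapshot_local_radii(snaps, b)
  ct <- cpp_nearest_contacts(as.numeric(snaps), n, k, as.integer(min_sep))
  d <- as.numeric(ct$distance)
  list(local = scale_mode(r, estimator, local_bin, local_xbin),
       nonlocal = scale_mode(d, estimator, nonlocal_bin, nonlocal_xbin),
       n_local = sum(is.finite(r)), n_nonlocal = length(d))
}

#' @rdname snapshot_length_scales
#' @export
snapshot_local_radii <- function(snaps, b) {
  n <- dim(snaps)[2]
  k <- dim(snaps)[3]
  # vectorized bending angles across all snapshots at once
  x <- matrix(aperm(snaps, c(2, 3, 1)), n * k, 3) # rows: bead-within-snap
  keep <- rep(seq_len(n - 2), k) # interior triplet starts per snapshot
  off <- rep((seq_len(k) - 1) * n, each = n - 2)
  i1 <- keep + off
  u <- x[i1, , drop = FALSE] - x[i1 + 1, , drop = FALSE]
  v <- x[i1 + 2, , drop = FALSE] - x[i1 + 1, , drop = FALSE]
  ct <- rowSums(u * v) / (sqrt(rowSums(u * u)) * sqrt(rowSums(v * v)))
  th <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  local_radius_from_theta(th, b)
}

#' Per-monomer scaled geometry profile
#'
#' The local radius at each interior monomer divided by its class's
#' characteristic local scale, and the nearest non-local contact distance
#' divided by the class's non-local scale.  For a chain that realizes its
#' class geometry ideally (e.g. an ideal helix scaled by the helix
#' scales), both series sit near 1.  Straight triplets give an infinite
#' scaled radius, which is reported as `Inf` and flagged.
#'
#' @param conf a `conformation`; labels are required unless a single pair
#'   of scales is given under the class `"none"` or the conformation is
#'   unlabeled (then the `"none"` scales apply everywhere).
#' @param scales named list: for each class present, a `c(local, nonlocal)`
#'   pair (angstrom), e.g. `list(alpha = c(2.73, 5.06))`.
#' @param min_sep minimum contact separation.
#' @return data.frame with `i`, `class`, `scaled_local` (NA at chain ends),
#'   `scaled_nonlocal`, `straight` flag.
#' @export
scaled_profile <- function(conf, scales, min_sep = 3L) {
  stopifnot(inherits(conf, "conformation"))
  n <- nrow(conf$coords)
  lab <- conf$labels
  if (is.null(lab)) lab <- rep("none", n)
  for (cl in unique(lab)) {
    sc <- scales[[cl]]
    if (is.null(sc) || length(sc) != 2 || any(!is.finite(sc)) || any(sc <= 0))
      stop("missing or invalid scale pair for class '", cl, "'")
  }
  loc_scale <- vapply(lab, function(cl) scales[[cl]][1], numeric(1))
  non_scale <- vapply(lab, function(cl) scales[[cl]][2], numeric(1))
  r <- c(NA_real_, local_radius_from_theta(chain_thetas(conf$coords),
                                           conf$b), NA_real_)
  d <- nearest_nonlocal_contact(conf, min_sep = min_sep)$distance
  data.frame(i = seq_len(n), class = lab,
             scaled_local = r / loc_scale,
             scaled_nonlocal = d / non_scale,
             straight = is.infinite(r))
}
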