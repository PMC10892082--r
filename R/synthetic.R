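#' Uniform random directions in d dimensions
#'
#' Normalized Gaussian vectors, the standard isotropic direction sampler.
#'
#' @param n number of directions.
#' @param d dimension >= 2.
#' @return n x d matrix of unit vectors.
#' @export
random_unit_vectors <- function(n, d) {
  v <- matrix(stats::rnorm(n * d), n, d)
  v / sqrt(rowSums(v * v))
}

#' Fixed-bond random walk
#'
#' A walk of `n_steps` independent uniformly-random directions, each of
#' length exactly `b`, in `d` dimensions (d = 2 walks are embedded in the
#' z = 0 plane).  This is the no-self-avoidance baseline whose triplet and
#' quartet inverse-radius CDFs have analytically known power laws.
#'
#' @param n_steps number of bonds (the walk has n_steps + 1 points).
#' @param d spatial dimension, 2 or 3 for conformation output.
#' @param b bond length in angstrom.
#' @return a `conformation` with n_steps + 1 points.
#' @export
random_walk <- function(n_steps, d = 3, b = 3.81) {
  if (n_steps < 1) stop("need at least one step")
  if (!d %in% c(2, 3))
    stop("conformation output supports d = 2 or 3; ",
         "use random_walk_batch() for higher dimensions")
  u <- random_unit_vectors(n_steps, d)
  if (d == 2) u <- cbind(u, 0)
  conformation(rbind(0, apply(u * b, 2, cumsum)), b = b)
}

#' Batch of fixed-bond random walks
#'
#' Generates `n_walks` independent walks of `n_steps` bonds in `d`
#' dimensions as a matrix, one walk per row with the points concatenated
#' (first point at the origin).  Works in any d >= 2; use
#' [walk_triplet_inverse_radii()] for circumradii in d > 3, where only
#' pairwise distances matter.
#'
#' @param n_walks number of walks.
#' @inheritParams random_walk
#' @return n_walks x ((n_steps + 1) * d) matrix.
#' @export
random_walk_batch <- function(n_walks, n_steps, d = 3, b = 3.81) {
  u <- random_unit_vectors(n_walks * n_steps, d) * b
  pts <- matrix(0, n_walks, (n_steps + 1) * d)
  acc <- matrix(0, n_walks, d)
  for (s in seq_len(n_steps)) {
    acc <- acc + u[((s - 1) * n_walks + 1):(s * n_walks), , drop = FALSE]
    pts[, (s * d + 1):((s + 1) * d)] <- acc
  }
  attr(pts, "d") <- d
  attr(pts, "b") <- b
  pts
}

#' Inverse circumradii of two-step walks in any dimension
#'
#' The circumradius of three points depends only on their pairwise
#' distances (R = abc / 4A with A from Heron's formula), so triplets of
#' walks in any ambient dimension reduce to the same computation.
#'
#' @param walks matrix from [random_walk_batch()] with `n_steps = 2`.
#' @return numeric vector of X = 1/R.
#' @export
walk_triplet_inverse_radii <- function(walks) {
  d <- attr(walks, "d")
  stopifnot(!is.null(d), ncol(walks) == 3 * d)
  p1 <- walks[, 1:d, drop = FALSE]
  p2 <- walks[, (d + 1):(2 * d), drop = FALSE]
  p3 <- walks[, (2 * d + 1):(3 * d), drop = FALSE]
  a <- sqrt(rowSums((p2 - p3)^2))
  b <- sqrt(rowSums((p1 - p3)^2))
  cc <- sqrt(rowSums((p1 - p2)^2))
  s16 <- 2 * (a^2 * b^2 + b^2 * cc^2 + cc^2 * a^2) - a^4 - b^4 - cc^4
  s16[s16 < 0] <- 0 # numerically collinear
  x <- sqrt(s16) / (a * b * cc)
  x[x < 1e-12] <- 0
  x
}

#' Constrained four-point random walk
#'
#' The first two steps are confined to a fixed plane (the first two points
#' along the x axis, the third placed at a uniformly random in-plane
#' direction), while the final step is a uniform direction in full 3D.
#' The mixed 2D/3D sampling makes the quartet inverse-radius CDF behave
#' like a walk in an effective fractal dimension between 2 and 3, with a
#' power-law exponent strictly between 1 and 2.
#'
#' @param b bond length in angstrom.
#' @return a 4-point `conformation`.
#' @export
constrained_random_walk <- function(b = 3.81) {
  conformation(constrained_walk_batch(1L, b)[1, , drop = TRUE] |>
                 matrix(4, 3, byrow = TRUE), b = b)
}

#' @rdname constrained_random_walk
#' @param n_walks number of walks.
#' @return for the batch version, an n_walks x 12 matrix of quartets.
#' @export
constrained_walk_batch <- function(n_walks, b = 3.81) {
  phi <- stats::runif(n_walks, 0, 2 * pi)
  u3 <- random_unit_vectors(n_walks, 3)
  p3 <- cbind(b + b * cos(phi), b * sin(phi), 0)
  cbind(matrix(0, n_walks, 3),
        cbind(b, 0, 0)[rep(1, n_walks), , drop = FALSE],
        p3,
        p3 + b * u3)
}

#' Uniform random points in a ball
#'
#' Independent points uniform in the 3D ball of the given radius, via the
#' radial inverse CDF r = radius * U^(1/3) times a uniform direction.
#' Unlike chain triplets, random ball points can form circles of
#' arbitrarily small radius, so their inverse-radius CDF has no steric
#' small-R cutoff.
#'
#' @param n_points number of points (>= 3).
#' @param radius ball radius.
#' @return n_points x 3 matrix.
#' @export
uniform_ball_points <- function(n_points, radius = 1) {
  if (n_points < 3) stop("need at least 3 points")
  u <- random_unit_vectors(n_points, 3)
  r <- radius * stats::runif(n_points)^(1 / 3)
  u * r
}

#' Short self-avoiding tangent-sphere walk
#'
#' Rejection-sampled fixed-bond walk whose points respect the tangent-
#' sphere hard core: all non-adjacent pairwise distances >= sigma (= b).
#' For a two-step walk this is exactly the steric bound theta >= 60
#' degrees on the bending angle.
#'
#' @param n_steps number of bonds.
#' @param b bond length (angstrom).
#' @param sigma hard-core diameter; the tangent model has sigma = b.
#' @param max_tries rejection-sampling cap.
#' @return a `conformation` with attribute `"acceptance"`, the fraction of
#'   proposals that were self-avoiding.
#' @export
self_avoiding_segment <- function(n_steps, b = 3.81, sigma = b,
                                  max_tries = 10000L) {
  for (k in seq_len(max_tries)) {
    w <- random_walk(n_steps, d = 3, b = b)
    if (!cpp_has_overlap(w$coords, sigma)) {
      attr(w, "acceptance") <- 1 / k
      return(w)
    }
  }
  stop("no self-avoiding walk found in ", max_tries, " tries")
}

#' @rdname self_avoiding_segment
#' @param n_walks number of walks to return.
#' @return for the batch version, a matrix of accepted walks (one per row,
#'   points concatenated) with attribute `"acceptance"`.
#' @export
self_avoiding_walk_batch <- function(n_walks, n_steps, b = 3.81, sigma = b) {
  npts <- n_steps + 1L
  out <- matrix(NA_real_, 0, 3 * npts)
  tried <- 0L
  while (nrow(out) < n_walks) {
    m <- max(1000L, ceiling((n_walks - nrow(out)) * 1.5))
    w <- random_walk_batch(m, n_steps, d = 3, b = b)
    tried <- tried + m
    ok <- rep(TRUE, m)
    s2 <- (sigma * (1 - 1e-9))^2
    for (i in 1:(npts - 2)) for (j in (i + 2):npts) {
      di <- w[, (3 * (i - 1) + 1):(3 * i), drop = FALSE] -
        w[, (3 * (j - 1) + 1):(3 * j), drop = FALSE]
      ok <- ok & rowSums(di * di) >= s2
    }
    out <- rbind(out, w[ok, , drop = FALSE])
  }
  out <- out[seq_len(n_walks), , drop = FALSE]
  attr(out, "d") <- 3L
  attr(out, "b") <- b
  attr(out, "acceptance") <- n_walks / tried
  out
}

#' Ideal alpha-helix C-alpha trace
#'
#' Points on a regular right-handed helix with the canonical C-alpha
#' parameters: rise 1.5 angstrom per residue, helix radius 2.3 angstrom,
#' twist 100 degrees per residue.  These give a C-alpha--C-alpha bond of
#' about 3.83 angstrom (within 0.05 of the canonical 3.81), a constant
#' bending angle theta of about 92 degrees and nearest non-local contacts
#' at sequence separation 3 at about 5.05 angstrom.
#'
#' @param n number of residues.
#' @param rise rise per residue (angstrom).
#' @param radius helix radius (angstrom).
#' @param twist twist per residue (degrees).
#' @param bond_target if non-NULL, error unless the implied bond length is
#'   within 0.05 angstrom of this value.
#' @return a `conformation` with all labels `"alpha"`.
#' @export
ideal_alpha_helix <- function(n = 30L, rise = 1.5, radius = 2.3,
                              twist = 100, bond_target = 3.81) {
  if (n < 2) stop("need at least 2 residues")
  phi <- (seq_len(n) - 1) * twist * pi / 180
  coords <- cbind(radius * cos(phi), radius * sin(phi),
                  (seq_len(n) - 1) * rise)
  bond <- sqrt((2 * radius * sin(twist * pi / 360))^2 + rise^2)
  if (!is.null(bond_target) && abs(bond - bond_target) > 0.05)
    stop("helix parameters imply bond ", format(bond),
         " A, more than 0.05 A from target ", bond_target)
  conformation(coords, b = bond, labels = rep("alpha", n))
}

#' Ideal beta-sheet C-alpha trace
#'
#' Planar zigzag strands (bending angle `zigzag_angle`, default 120
#' degrees) stacked with an inter-strand spacing chosen so that
#' cross-strand nearest distances fall below 6 angstrom, joined by short
#' circular-arc turns whose beads are labeled `"loop"`.  `topology`
#' selects parallel strands (same direction, long connecting loop, near
#' contacts at roughly constant j - i >= 4) or an antiparallel hairpin
#' (near contacts at roughly constant i + j).
#'
#' @param strand_lengths integer vector, residues per strand.
#' @param zigzag_angle strand interior bending angle (degrees).
#' @param spacing inter-strand spacing (angstrom).
#' @param topology `"antiparallel"` or `"parallel"`.
#' @param b bond length (angstrom).
#' @return a `conformation` with labels `"beta"` on strands and `"loop"`
#'   on turns.
#' @export
ideal_beta_sheet <- function(strand_lengths = c(8L, 8L), zigzag_angle = 120,
                             spacing = 4.8,
                             topology = c("antiparallel", "parallel"),
                             b = 3.81) {
  topology <- match.arg(topology)
  if (length(strand_lengths) < 2) stop("need at least two strands")
  sx <- b * sin(zigzag_angle * pi / 360)
  h <- b * cos(zigzag_angle * pi / 360)
  coords <- NULL
  labels <- character(0)
  for (k in seq_along(strand_lengths)) {
    len <- strand_lengths[k]
    t <- seq_len(len) - 1
    y <- (t %% 2) * h
    z <- (k - 1) * spacing
    backward <- topology == "antiparallel" && k %% 2 == 0
    xmax <- (max(strand_lengths) - 1) * sx
    x <- if (backward) xmax - t * sx else t * sx
    strand <- cbind(x, y, z)
    if (is.null(coords)) {
      coords <- strand
      labels <- rep("beta", len)
    } else {
      bridge <- arc_bridge(coords[nrow(coords), ], strand[1, ], b,
                           out_dir = turn_out_direction(coords, strand))
      coords <- rbind(coords, bridge, strand)
      labels <- c(labels, rep("loop", nrow(bridge)), rep("beta", len))
    }
  }
  conformation(coords, b = b, labels = labels)
}

# direction in which a turn should bulge: outward along the strand axis,
# orthogonalized against the turn chord
turn_out_direction <- function(coords, strand) {
  last_bond <- coords[nrow(coords), ] - coords[nrow(coords) - 1, ]
  chord <- strand[1, ] - coords[nrow(coords), ]
  e1 <- chord / sqrt(sum(chord^2))
  v <- last_bond - sum(last_bond * e1) * e1
  nv <- sqrt(sum(v * v))
  if (nv < 1e-9) { # chord parallel to strand: bulge perpendicular in-plane
    v <- c(-e1[2], e1[1], 0)
    nv <- sqrt(sum(v * v))
    if (nv < 1e-9) { v <- c(0, -e1[3], e1[2]); nv <- sqrt(sum(v * v)) }
  }
  v / nv
}

# equal-chord circular arc from P to Q: m bonds of length exactly b, the
# m - 1 interior points returned; bulges toward out_dir
arc_bridge <- function(P, Q, b, out_dir, m = NULL) {
  L <- sqrt(sum((Q - P)^2))
  if (is.null(m)) m <- max(2L, ceiling(L / b) + 1L)
  if (m * b <= L + 1e-9) stop("bridge too short: increase m")
  # chord of circle: b = 2 rho sin(t), L = 2 rho sin(m t); solve for t
  f <- function(t) sin(m * t) / sin(t) - L / b
  t <- stats::uniroot(f, c(1e-9, pi / m - 1e-9), tol = 1e-14)$root
  rho <- b / (2 * sin(t))
  e1 <- (Q - P) / L
  e2 <- out_dir - sum(out_dir * e1) * e1
  e2 <- e2 / sqrt(sum(e2 * e2))
  ctr <- (P + Q) / 2 - rho * cos(m * t) * e2
  # in the (e1, e2) basis about the center, P sits at angle pi/2 + m t and
  # each chord advances the angle by -2 t toward Q at pi/2 - m t
  phi <- pi / 2 + m * t - 2 * t * seq_len(m - 1)
  t(vapply(phi, function(a) ctr + rho * (cos(a) * e1 + sin(a) * e2),
           numeric(3)))
}

#' Concatenate labeled chain segments
#'
#' Joins a list of `conformation` segments into one chain, translating each
#' segment so that its first bead continues from the previous segment's end
#' along the direction of the last bond (so the joining bond has length
#' exactly b).  All segments must share the same bond length to within
#' 1e-6 angstrom.  Optional isotropic Gaussian jitter perturbs every
#' coordinate; with jitter the result no longer claims fixed bonds.
#'
#' @param segments list of `conformation` objects.
#' @param jitter_sd standard deviation of the coordinate jitter (angstrom);
#'   0 keeps the segment geometries exact.
#' @param b_tol largest allowed spread of the segments' bond lengths
#'   (angstrom); the ideal-helix bond (about 3.83) and the canonical 3.81
#'   must coexist in mixed fixtures.
#' @return a `conformation` carrying the concatenated ground-truth labels
#'   (segments without labels contribute `"none"`).  The result claims
#'   fixed bonds only when the segments agree on `b` exactly and no jitter
#'   is applied.
#' @export
compose_labeled_chain <- function(segments, jitter_sd = 0, b_tol = 0.05) {
  stopifnot(length(segments) >= 1,
            all(vapply(segments, inherits, logical(1), "conformation")))
  bs <- vapply(segments, `[[`, numeric(1), "b")
  b <- bs[1]
  if (any(abs(bs - b) > b_tol))
    stop("segments disagree on bond length by more than ", b_tol, " A")
  coords <- segments[[1]]$coords
  labels <- segment_labels(segments[[1]])
  for (s in segments[-1]) {
    nlast <- nrow(coords)
    dir <- coords[nlast, ] - coords[nlast - 1, ]
    dir <- dir / sqrt(sum(dir^2))
    shift <- coords[nlast, ] + s$b * dir - s$coords[1, ]
    coords <- rbind(coords, sweep(s$coords, 2, shift, "+"))
    labels <- c(labels, segment_labels(s))
  }
  if (jitter_sd > 0)
    coords <- coords + matrix(stats::rnorm(length(coords), 0, jitter_sd),
                              nrow(coords), 3)
  exact <- jitter_sd == 0 && all(abs(bs - b) <= 1e-9 * b)
  conformation(coords, b = b, labels = labels, fixed_bonds = exact)
}

segment_labels <- function(s) {
  if (is.null(s$labels)) rep("none", nrow(s$coords)) else s$labels
}
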