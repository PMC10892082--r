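#' Bond-bending angle at a vertex
#'
#' Angle theta at `p2` between the segments `p2 -> p1` and `p2 -> p3`, in
#' degrees.  A locally straight chain (p2 between collinear p1, p3) has
#' theta = 180 degrees; theta near 0 means the chain folds back onto
#' itself.  This is the standard backbone bond-bending angle for
#' C-alpha traces.
#'
#' @param p1,p2,p3 numeric 3-vectors (angstrom).
#' @return angle in degrees, in (0, 180].
#' @examples
#' bond_bending_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)) # 180
#' bond_bending_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)) # 90
#' @export
bond_bending_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  nu <- sqrt(sum(u * u))
  nv <- sqrt(sum(v * v))
  if (nu < 1e-12 || nv < 1e-12)
    stop("coincident points: bond-bending angle undefined")
  ct <- sum(u * v) / (nu * nv)
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

#' Signed dihedral (torsional) angle of four points
#'
#' The torsion about the `p2 -> p3` axis, equivalently the signed angle
#' between the successive binormals of the two bond-angle planes.  The sign
#' is right-handed about `p2 -> p3`; a coplanar quartet gives 0 (cis-like)
#' or 180 (trans-like).  Returned in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (angstrom).
#' @return signed angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1 * n1) < 1e-20 || sum(n2 * n2) < 1e-20)
    stop("collinear interior triplet: binormal (and dihedral) undefined")
  nb2 <- sqrt(sum(b2 * b2))
  mu <- atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2)) * 180 / pi
  if (mu <= -180) mu <- mu + 360
  mu
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Radius of the circle through three points (three-body radius)
#'
#' Computed as R = abc / 4A from the side lengths a, b, c and the triangle
#' area A.  For a local chain triplet this is the discrete radius of
#' curvature; for a non-local triplet it measures the closest approach of
#' two chain segments.  Near-collinear triplets, where 4A/(abc) falls below
#' `collinear_tol` (1/angstrom), are flagged as infinite radius: an
#' infinitely large three-body radius signals collinearity of the points.
#'
#' @param p1,p2,p3 numeric 3-vectors (angstrom).
#' @param collinear_tol collinearity threshold on 1/R (1/angstrom).
#' @return a `radius_sample`: list with `R` (angstrom, possibly `Inf`),
#'   `X` = 1/R (0 when infinite) and `order = 3`.
#' @examples
#' circumradius_triplet(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))$R
#' @export
circumradius_triplet <- function(p1, p2, p3, collinear_tol = 1e-12) {
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  cc <- sqrt(sum((p1 - p2)^2))
  if (a < 1e-12 || b < 1e-12 || cc < 1e-12)
    stop("coincident points: circumradius undefined")
  # X = 1/R = 4A/(abc); area via cross product for numerical robustness
  ar2 <- cross3(p2 - p1, p3 - p1)
  area <- 0.5 * sqrt(sum(ar2 * ar2))
  x <- 4 * area / (a * b * cc)
  if (x < collinear_tol)
    radius_sample(Inf, order = 3L)
  else
    radius_sample(1 / x, order = 3L)
}

#' Radius of the sphere through four points (four-body radius)
#'
#' The center equidistant from the four points solves a 3x3 linear system;
#' the radius is its distance to any of the points.  Coplanar quartets make
#' the system singular and are flagged as infinite radius: an infinite
#' four-body radius is associated with planarity of the quartet.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (angstrom).
#' @param det_tol relative determinant threshold below which the quartet is
#'   declared coplanar.
#' @return a `radius_sample` with `order = 4` and, for finite radii, the
#'   sphere `center`.
#' @export
circumsphere_radius_quartet <- function(p1, p2, p3, p4, det_tol = 1e-12) {
  pts <- rbind(p1, p2, p3, p4)
  if (any(dist(pts) < 1e-12))
    stop("coincident points: circumsphere undefined")
  A <- 2 * sweep(pts[2:4, , drop = FALSE], 2, pts[1, ], "-")
  rhs <- rowSums(pts[2:4, , drop = FALSE]^2) - sum(pts[1, ]^2)
  scale <- mean(sqrt(rowSums(A^2)))
  if (abs(det(A)) < det_tol * scale^3)
    return(radius_sample(Inf, order = 4L))
  center <- solve(A, rhs)
  out <- radius_sample(sqrt(sum((pts[1, ] - center)^2)), order = 4L)
  out$center <- as.numeric(center)
  out
}

#' @rdname circumradius_triplet
#' @param R radius in angstrom (`Inf` allowed).
#' @param order 3 for triplet circles, 4 for quartet spheres.
#' @export
radius_sample <- function(R, order = 3L) {
  if (R < 0) stop("negative radius")
  structure(list(R = R, X = if (is.finite(R)) 1 / R else 0,
                 order = as.integer(order)),
            class = "radius_sample")
}

#' Local radius of curvature from the bond-bending angle
#'
#' For a fixed-bond chain the circumradius of a local triplet depends only
#' on the bending angle: R = b / (2 cos(theta / 2)).  A straight triplet
#' (theta = 180 degrees) has infinite local radius; the tangent-sphere
#' steric floor theta >= 60 degrees maps to R >= b / sqrt(3).
#'
#' @param theta bending angle in degrees, in (0, 180].
#' @param b bond length in angstrom.
#' @return local radius in angstrom (`Inf` at theta = 180).
#' @export
local_radius_from_theta <- function(theta, b) {
  if (any(theta <= 0 | theta > 180)) stop("theta must lie in (0, 180]")
  if (b <= 0) stop("bond length must be positive")
  ct <- cos(theta * pi / 360) # theta/2 in radians
  ifelse(ct < 1e-15, Inf, b / (2 * ct))
}

#' Bending and dihedral angle map of a chain
#'
#' One (theta, mu) pair per interior position that admits both angles.
#' For a chain of n monomers there are n - 2 bending angles (vertices
#' 2..n-1) and n - 3 dihedrals (bond axes 2-3 .. (n-2)-(n-1)); the map
#' pairs theta at vertex i+1 with mu of the quartet (i, i+1, i+2, i+3) for
#' i = 1..n-3, i.e. the theta of the quartet's first interior vertex.
#' Dihedrals with a collinear interior triplet are returned as `NA`.
#'
#' @param conf a `conformation` with n >= 4.
#' @return data.frame with columns `i` (quartet start index), `theta`,
#'   `mu` (degrees).
#' @export
theta_mu_map <- function(conf) {
  stopifnot(inherits(conf, "conformation"))
  x <- conf$coords
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 monomers for a (theta, mu) map")
  th <- chain_thetas(x)            # length n - 2, vertex i+1 for i = 1..n-2
  mu <- chain_dihedrals(x)         # length n - 3
  data.frame(i = seq_len(n - 3L), theta = th[seq_len(n - 3L)], mu = mu)
}

# vectorized bending angles at vertices 2..n-1 (degrees)
chain_thetas <- function(x) {
  n <- nrow(x)
  u <- x[1:(n - 2), , drop = FALSE] - x[2:(n - 1), , drop = FALSE]
  v <- x[3:n, , drop = FALSE] - x[2:(n - 1), , drop = FALSE]
  ct <- rowSums(u * v) / (sqrt(rowSums(u * u)) * sqrt(rowSums(v * v)))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

# vectorized signed dihedrals for quartets starting at 1..n-3 (degrees)
chain_dihedrals <- function(x) {
  n <- nrow(x)
  b1 <- x[2:(n - 2), , drop = FALSE] - x[1:(n - 3), , drop = FALSE]
  b2 <- x[3:(n - 1), , drop = FALSE] - x[2:(n - 2), , drop = FALSE]
  b3 <- x[4:n, , drop = FALSE] - x[3:(n - 1), , drop = FALSE]
  n1 <- rowcross(b1, b2)
  n2 <- rowcross(b2, b3)
  s1 <- rowSums(n1 * n1)
  s2 <- rowSums(n2 * n2)
  y <- rowSums(rowcross(n1, n2) * b2) / sqrt(rowSums(b2 * b2))
  mu <- atan2(y, rowSums(n1 * n2)) * 180 / pi
  mu[s1 < 1e-20 | s2 < 1e-20] <- NA_real_
  mu[!is.na(mu) & mu <= -180] <- mu[!is.na(mu) & mu <= -180] + 360
  mu
}

rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Nearest non-local contact of every monomer
#'
#' For each monomer i, the partner j minimizing the Euclidean distance
#' subject to the non-locality constraint |i - j| >= `min_sep` (default 3,
#' the standard definition for backbone contacts).  Ties are broken to the
#' smallest j.
#'
#' @param conf a `conformation` with more than `min_sep` monomers.
#' @param min_sep minimum sequence separation.
#' @return data.frame of contact records: `i`, `j`, `distance` (angstrom),
#'   `separation` = |i - j|.
#' @export
nearest_nonlocal_contact <- function(conf, min_sep = 3L) {
  stopifnot(inherits(conf, "conformation"))
  n <- nrow(conf$coords)
  if (n <= min_sep) {
    warning("chain too short for non-local contacts at min_sep = ", min_sep)
    return(data.frame(i = integer(), j = integer(),
                      distance = numeric(), separation = integer()))
  }
  res <- cpp_nearest_contacts(as.numeric(t(conf$coords)), n, 1L,
                              as.integer(min_sep))
  data.frame(i = seq_len(n), j = res$j[, 1], distance = res$distance[, 1],
             separation = abs(seq_len(n) - res$j[, 1]))
}

#' Nearest-contact map with a near/far flag
#'
#' The nearest non-local contact records of [nearest_nonlocal_contact()]
#' with a `near` flag marking contacts found within `threshold` (default
#' 6 angstrom, the pronounced minimum of the protein radial distribution
#' function).
#'
#' @inheritParams nearest_nonlocal_contact
#' @param threshold near/far distance threshold in angstrom.
#' @return contact data.frame with an extra logical column `near`.
#' @export
contact_map <- function(conf, threshold = 6.0, min_sep = 3L) {
  rec <- nearest_nonlocal_contact(conf, min_sep = min_sep)
  rec$near <- rec$distance <= threshold
  rec
}

#' Write a contact map to CSV
#'
#' Columns: `i`, `j`, `distance` (angstrom), `separation`, `near`
#' (TRUE/FALSE).
#'
#' @param contacts data.frame from [contact_map()].
#' @param path output path.
#' @export
write_contact_csv <- function(contacts, path) {
  utils::write.csv(contacts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
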