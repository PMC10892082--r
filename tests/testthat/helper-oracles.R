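# Independent oracles used across the suite.  These deliberately avoid the
# package's own kernels: brute-force scans, rejection sampling and closed
# forms only.

# nearest non-local partner by exhaustive scan
brute_nearest <- function(coords, min_sep = 3L) {
  n <- nrow(coords)
  t(vapply(seq_len(n), function(i) {
    best <- Inf
    bj <- NA_integer_
    for (j in seq_len(n)) {
      if (abs(i - j) < min_sep) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d < best) { best <- d; bj <- j }
    }
    c(bj, best)
  }, numeric(2)))
}

# uniform self-avoiding tangent-chain conformations by rejection from
# plain fixed-bond walks (exact for small n)
rejection_saw <- function(n_conf, n_beads, b = 3.81) {
  out <- vector("list", n_conf)
  k <- 0L
  while (k < n_conf) {
    w <- random_walk(n_beads - 1L, d = 3, b = b)
    d <- as.matrix(dist(w$coords))
    ok <- TRUE
    for (i in 1:(n_beads - 2)) for (j in (i + 2):n_beads)
      if (d[i, j] < b * (1 - 1e-9)) { ok <- FALSE; break }
    if (ok) { k <- k + 1L; out[[k]] <- w }
  }
  out
}

# exact two-level-system thermodynamics: energies 0 (degeneracy g0) and
# -1 (degeneracy g1), k_B = 1
two_level_cv <- function(T, g0, g1) {
  z <- g0 + g1 * exp(1 / T)
  m1 <- -g1 * exp(1 / T) / z
  m2 <- g1 * exp(1 / T) / z
  (m2 - m1^2) / T^2
}

two_level_sample <- function(n, T, g0, g1) {
  p1 <- g1 * exp(1 / T) / (g0 + g1 * exp(1 / T))
  ifelse(stats::runif(n) < p1, -1, 0)
}

random_rotation_oracle <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
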