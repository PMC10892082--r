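#' Square-well tangent-sphere chain model
#'
#' The minimal attractive homopolymer: n hard spheres of diameter sigma
#' tethered with bond length exactly sigma (consecutive spheres touch,
#' hence "tangent"), with a square-well attraction of range
#' `R_att = 1.6 sigma` and depth epsilon between all non-adjacent pairs.
#' Epsilon sets the energy unit, so energies are integer contact counts
#' times -epsilon and temperatures are reduced (k_B T / epsilon).
#'
#' @param n chain length (number of beads).
#' @param sigma hard-sphere diameter = bond length, angstrom.
#' @param epsilon well depth (energy unit).
#' @param range_factor attraction range in units of sigma.
#' @return a `square_well_model`.
#' @export
square_well_model <- function(n = 80L, sigma = 3.81, epsilon = 1,
                              range_factor = 1.6) {
  stopifnot(n >= 2, sigma > 0, epsilon > 0, range_factor > 1)
  structure(list(n = as.integer(n), sigma = sigma, epsilon = epsilon,
                 R_att = range_factor * sigma),
            class = "square_well_model")
}

#' @export
print.square_well_model <- function(x, ...) {
  cat("<square_well_model> n = ", x$n, ", sigma = b = ", format(x$sigma),
      " A, R_att = ", format(x$R_att), " A, epsilon = ", format(x$epsilon),
      "\n", sep = "")
  invisible(x)
}

#' Default replica-exchange temperature ladder
#'
#' Reduced temperatures with a finer mesh at the low end: 0.3 to 0.5 in
#' steps of 0.02, 0.5 to 1 in steps of 0.05, and 1 to 4 in steps of 0.2
#' (36 temperatures).  The fine low-temperature mesh keeps neighbouring
#' energy histograms overlapping through the collapse region so swap
#' acceptance stays usable.
#'
#' @param t_max upper end of the ladder (allows truncated desk-scale
#'   ladders while keeping the mesh).
#' @return increasing numeric vector of reduced temperatures.
#' @export
replica_ladder <- function(t_max = 4) {
  temps <- c(seq(0.3, 0.5, by = 0.02),
             seq(0.55, 1, by = 0.05),
             seq(1.2, 4, by = 0.2))
  unique(temps[temps <= t_max + 1e-9])
}

#' Square-well energy of a conformation
#'
#' -epsilon times the number of non-adjacent pairs (|i - j| >= 2) within
#' the attraction range.  Errors if the conformation violates the hard
#' core (any non-adjacent pair closer than sigma, to 1e-9 relative).
#'
#' @param conf a `conformation`.
#' @param model a `square_well_model`.
#' @return energy in units of epsilon (a non-positive multiple of epsilon).
#' @export
total_energy <- function(conf, model) {
  stopifnot(inherits(conf, "conformation"),
            inherits(model, "square_well_model"))
  d <- as.matrix(stats::dist(conf$coords))
  n <- nrow(d)
  nonadj <- abs(row(d) - col(d)) >= 2 & upper.tri(d)
  if (any(d[nonadj] < model$sigma * (1 - 1e-9)))
    stop("conformation violates the hard core")
  -model$epsilon * sum(d[nonadj] <= model$R_att)
}

#' Propose one elementary chain move
#'
#' Draws one of the four bond-preserving move types with equal probability
#' (or applies a requested one) and returns the candidate conformation:
#' crankshaft (rotate an interior bead about the chord of its neighbours by
#' a uniform angle in (-pi, pi]), reptation (delete one end bead, regrow a
#' uniformly-directed bond at the other end), endpoint (re-point a terminal
#' bond uniformly on the sphere) and pivot (rigid uniformly-random rotation
#' of one chain arm about an interior bead).  All moves preserve every bond
#' length exactly; acceptance is decided downstream by
#' [metropolis_step()].
#'
#' @param conf a `conformation`.
#' @param move_type one of `"crankshaft"`, `"reptation"`, `"endpoint"`,
#'   `"pivot"`, or `NULL` to draw uniformly.
#' @return the candidate `conformation` with attribute `"move_type"`.
#' @export
propose_move <- function(conf, move_type = NULL) {
  stopifnot(inherits(conf, "conformation"))
  x <- conf$coords
  n <- nrow(x)
  b <- conf$b
  types <- c("crankshaft", "reptation", "endpoint", "pivot")
  if (is.null(move_type)) move_type <- sample(types, 1)
  move_type <- match.arg(move_type, types)
  if (move_type == "crankshaft") {
    i <- sample(2:(n - 1), 1)
    ax <- x[i + 1, ] - x[i - 1, ]
    ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, -pi, pi)
    v <- x[i, ] - x[i - 1, ]
    x[i, ] <- x[i - 1, ] + rodrigues(v, ax, ang)
  } else if (move_type == "endpoint") {
    i <- sample(c(1L, n), 1)
    nb <- if (i == 1L) 2L else n - 1L
    x[i, ] <- x[nb, ] + b * drop(random_unit_vectors(1, 3))
  } else if (move_type == "reptation") {
    if (stats::runif(1) < 0.5) {
      x <- rbind(x[-1, , drop = FALSE],
                 x[n, ] + b * drop(random_unit_vectors(1, 3)))
    } else {
      x <- rbind(x[1, ] + b * drop(random_unit_vectors(1, 3)),
                 x[-n, , drop = FALSE])
    }
  } else { # pivot
    i <- sample(2:(n - 1), 1)
    R <- random_rotation_matrix()
    idx <- if (stats::runif(1) < 0.5) (i + 1):n else 1:(i - 1)
    x[idx, ] <- sweep(sweep(x[idx, , drop = FALSE], 2, x[i, ], "-") %*% t(R),
                      2, x[i, ], "+")
  }
  out <- conformation(x, b = b, labels = conf$labels)
  attr(out, "move_type") <- move_type
  out
}

rodrigues <- function(v, u, ang) {
  ca <- cos(ang); sa <- sin(ang)
  v * ca + cross3(u, v) * sa + u * sum(u * v) * (1 - ca)
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' One Metropolis step
#'
#' Proposes a move and applies the standard Metropolis rule at reduced
#' temperature `reduced_T`: candidates violating the hard core are always
#' rejected; otherwise accept with min(1, exp(-dE / k_B T)).  At
#' `reduced_T = Inf` every self-avoiding candidate is accepted.
#'
#' @param conf current `conformation`.
#' @param model a `square_well_model`.
#' @param reduced_T reduced temperature k_B T / epsilon (> 0 or `Inf`).
#' @param move_type optional forced move type, see [propose_move()].
#' @return list with `conf` (new or unchanged), `accepted`, `energy`.
#' @export
metropolis_step <- function(conf, model, reduced_T, move_type = NULL) {
  stopifnot(reduced_T > 0)
  e_old <- total_energy(conf, model)
  cand <- propose_move(conf, move_type)
  if (cpp_has_overlap(cand$coords, model$sigma))
    return(list(conf = conf, accepted = FALSE, energy = e_old))
  e_new <- total_energy(cand, model)
  de <- e_new - e_old
  acc <- de <= 0 || !is.finite(reduced_T) ||
    stats::runif(1) < exp(-de / (reduced_T * model$epsilon))
  if (acc) list(conf = cand, accepted = TRUE, energy = e_new)
  else list(conf = conf, accepted = FALSE, energy = e_old)
}

#' Infinite-temperature sampling of the tangent chain
#'
#' Metropolis MC in which every proposed update that respects
#' self-avoidance is accepted, giving uniform sampling over self-avoiding
#' tangent-chain conformations.  The move set includes the non-local pivot
#' for decorrelation.  Runs in compiled code; one sweep is n elementary
#' move attempts.
#'
#' @param model a `square_well_model` (only sigma and n matter at T = Inf).
#' @param sweeps total MC sweeps.
#' @param burnin sweeps discarded before sampling.
#' @param snapshot_stride sweeps between stored conformations.
#' @param init optional initial `conformation`; default straight chain.
#' @return list with `snapshots` (3 x n x k array), `energies` (contact
#'   energies of the snapshots' trace), `acceptance` (per move type),
#'   and `model`.
#' @export
run_infinite_temperature <- function(model, sweeps = 20000L, burnin = 2000L,
                                     snapshot_stride = 2L, init = NULL) {
  stopifnot(inherits(model, "square_well_model"))
  if (is.null(init)) init <- straight_chain(model$n, model$sigma)
  res <- cpp_run_mc(init$coords, model$sigma, model$R_att, -1,
                    as.integer(sweeps), as.integer(burnin),
                    1L, as.integer(snapshot_stride))
  acc <- res$accepts / pmax(res$attempts, 1)
  names(acc) <- c("crankshaft", "endpoint", "reptation", "pivot")
  list(snapshots = res$snapshots, energies = res$energies,
       acceptance = acc, model = model)
}

#' Replica-exchange Monte Carlo of the square-well chain
#'
#' Parallel canonical simulations at the ladder temperatures with
#' configuration swaps attempted between neighbouring temperatures every
#' `swap_stride` sweeps (accepted with the standard criterion
#' min(1, exp(dBeta * dE))).  Per-replica energy traces feed
#' [wham_specific_heat()]; conformation snapshots are collected at the
#' requested ladder temperatures.
#'
#' @param model a `square_well_model`.
#' @param ladder increasing reduced temperatures (see [replica_ladder()]).
#' @param sweeps MC sweeps per replica.
#' @param burnin sweeps discarded before sampling.
#' @param swap_stride sweeps between swap attempts.
#' @param sample_stride sweeps between energy samples.
#' @param snapshot_temps reduced temperatures at which to store snapshots
#'   (must be ladder members).
#' @param snapshot_stride sweeps between snapshots.
#' @param init optional initial `conformation`.
#' @return an `energy_traces` object: list with `traces` (list of numeric
#'   energy vectors, units of epsilon), `temperatures`, `snapshots` (named
#'   list of 3 x n x k arrays), `swap_acceptance`, `move_acceptance`,
#'   `model` and the strides.
#' @export
run_replica_exchange <- function(model, ladder = replica_ladder(),
                                 sweeps = 20000L, burnin = 5000L,
                                 swap_stride = 10L, sample_stride = 10L,
                                 snapshot_temps = numeric(0),
                                 snapshot_stride = 10L, init = NULL) {
  stopifnot(inherits(model, "square_well_model"),
            all(diff(ladder) > 0), all(ladder > 0))
  if (is.null(init)) init <- straight_chain(model$n, model$sigma)
  snap_idx <- integer(0)
  if (length(snapshot_temps)) {
    snap_idx <- vapply(snapshot_temps, function(tt) {
      k <- which(abs(ladder - tt) < 1e-9)
      if (!length(k)) stop("snapshot temperature ", tt, " not in ladder")
      k[1]
    }, integer(1))
  }
  res <- cpp_run_re(init$coords, model$sigma, model$R_att, ladder,
                    as.integer(sweeps), as.integer(burnin),
                    as.integer(swap_stride), as.integer(sample_stride),
                    as.integer(snap_idx), as.integer(snapshot_stride))
  if (length(ladder) > 1 && any(res$swap_acceptance < 0.01, na.rm = TRUE))
    warning("some neighbour swap acceptances are below 1%: ",
            "energy histograms barely overlap")
  acc <- res$accepts / pmax(res$attempts, 1)
  names(acc) <- c("crankshaft", "endpoint", "reptation", "pivot")
  snaps <- res$snapshots
  names(snaps) <- as.character(snapshot_temps)
  structure(list(traces = res$energies, temperatures = ladder,
                 snapshots = snaps, swap_acceptance = res$swap_acceptance,
                 move_acceptance = acc, model = model,
                 sweeps = sweeps, burnin = burnin,
                 sample_stride = sample_stride),
            class = "energy_traces")
}

#' @export
print.energy_traces <- function(x, ...) {
  cat("<energy_traces> ", length(x$traces), " replicas, ",
      length(x$traces[[1]]), " samples each, T in [",
      format(min(x$temperatures)), ", ", format(max(x$temperatures)),
      "]\n", sep = "")
  if (length(x$swap_acceptance))
    cat("  mean neighbour swap acceptance ",
        format(mean(x$swap_acceptance), digits = 3), "\n", sep = "")
  invisible(x)
}

#' WHAM specific heat from multi-temperature energy traces
#'
#' Estimates the density of states over the discrete square-well energy
#' levels by the self-consistent weighted-histogram iteration (free-energy
#' shifts iterated to `tol`), then evaluates the specific heat per bead
#' C_V / (N k_B) = (<E^2> - <E>^2) / (n T^2) on a reduced-temperature
#' grid.
#'
#' @param traces an `energy_traces` object, or a list of numeric energy
#'   vectors with `temperatures` supplied.
#' @param T_grid reduced temperatures at which to evaluate C_V.
#' @param temperatures ladder temperatures when `traces` is a bare list.
#' @param n number of beads (taken from the model when available).
#' @param tol convergence tolerance on the free-energy shifts.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return a `heat_capacity_curve`: data.frame with columns `T` and `cv`
#'   (C_V / N k_B), with the estimated log density of states as attribute
#'   `"log_g"`.
#' @export
wham_specific_heat <- function(traces, T_grid, temperatures = NULL,
                               n = NULL, tol = 1e-8, max_iter = 10000L) {
  if (inherits(traces, "energy_traces")) {
    temperatures <- traces$temperatures
    if (is.null(n)) n <- traces$model$n
    traces <- traces$traces
  }
  stopifnot(is.list(traces), length(traces) >= 1,
            length(temperatures) == length(traces))
  if (is.null(n)) stop("supply the number of beads `n`")
  if (any(T_grid <= 0)) stop("T_grid must be positive")
  allE <- unlist(traces)
  if (any(allE > 0)) stop("square-well energies must be non-positive")
  levels <- sort(unique(allE))
  nrep <- length(traces)
  H <- vapply(traces, function(e)
    tabulate(match(e, levels), length(levels)), numeric(length(levels)))
  H <- matrix(H, nrow = length(levels))
  N <- vapply(traces, length, numeric(1))
  beta <- 1 / temperatures
  logN <- log(N)
  f <- rep(0, nrep) # dimensionless free energies f_r = -log Z_r (shifted)
  Htot <- rowSums(H)
  # log denominator matrix pieces: log N_r + f_r - beta_r E
  bE <- outer(levels, beta) # levels x nrep, beta_r * E
  iter <- 0L
  repeat {
    iter <- iter + 1L
    logw <- sweep(-bE, 2, logN + f, "+") # log(N_r exp(f_r - beta_r E))
    logden <- apply(logw, 1, logsumexp)
    logg <- ifelse(Htot > 0, log(Htot) - logden, -Inf)
    fnew <- -vapply(seq_len(nrep), function(r)
      logsumexp(logg - bE[, r]), numeric(1))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) break
    if (iter >= max_iter)
      stop("WHAM did not converge: residual ", format(delta),
           " after ", max_iter, " iterations")
  }
  cv <- vapply(T_grid, function(tt) {
    lw <- logg - levels / tt
    lw <- lw - logsumexp(lw)
    w <- exp(lw)
    m1 <- sum(w * levels)
    m2 <- sum(w * levels^2)
    (m2 - m1^2) / (n * tt^2)
  }, numeric(1))
  out <- data.frame(T = T_grid, cv = cv)
  attr(out, "log_g") <- data.frame(E = levels, log_g = logg)
  attr(out, "iterations") <- iter
  class(out) <- c("heat_capacity_curve", "data.frame")
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Direct fluctuation estimate of the specific heat
#'
#' C_V / N k_B from the energy variance of a single canonical trace at its
#' own temperature -- the degenerate single-histogram case that WHAM must
#' reproduce.
#'
#' @param energies numeric energy samples (units of epsilon).
#' @param reduced_T the trace's reduced temperature.
#' @param n number of beads.
#' @return C_V / (N k_B).
#' @export
fluctuation_cv <- function(energies, reduced_T, n) {
  stats::var(energies) * (length(energies) - 1) / length(energies) /
    (n * reduced_T^2)
}

#' Energy autocorrelation time
#'
#' Integrated autocorrelation time of an energy trace (in sample strides),
#' the standard convergence diagnostic logged by the pipeline.
#'
#' @param energies numeric energy samples.
#' @param max_lag window cap.
#' @return estimated integrated autocorrelation time.
#' @export
energy_autocorrelation_time <- function(energies,
                                        max_lag = min(1000L,
                                                      length(energies) %/% 4L)) {
  if (stats::var(energies) == 0) return(1)
  ac <- stats::acf(energies, lag.max = max_lag, plot = FALSE)$acf[, 1, 1]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1] else length(ac)
  1 + 2 * sum(ac[2:cut])
}
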