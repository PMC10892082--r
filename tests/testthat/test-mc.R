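test_that("square-well energy counts non-adjacent contacts", {
  model <- square_well_model(n = 10)
  expect_equal(model$R_att, 1.6 * 3.81)
  s <- straight_chain(10)
  expect_equal(total_energy(s, model), 0) # all non-adjacent pairs >= 2 sigma
  # isoceles triplet with the end pair at exactly 1.5 sigma: one contact
  b <- 3.81
  th <- 2 * asin(0.75) # vertex angle giving chord 1.5 b
  p <- rbind(c(b * sin(th / 2), b * cos(th / 2), 0), c(0, 0, 0),
             c(-b * sin(th / 2), b * cos(th / 2), 0))
  conf3 <- conformation(p, b = b)
  expect_equal(sqrt(sum((p[3, ] - p[1, ])^2)), 1.5 * b, tolerance = 1e-9)
  expect_equal(total_energy(conf3, square_well_model(n = 3)), -1)
  # adjacent pairs at sigma contribute nothing
  expect_equal(total_energy(straight_chain(2), square_well_model(n = 2)), 0)
  # hard-core violation is an error
  bad <- conformation(rbind(c(0, 0, 0), c(b, 0, 0), c(b, b, 0),
                            c(0.1, 0.05, 0)), b = b, fixed_bonds = FALSE)
  expect_error(total_energy(bad, square_well_model(n = 4)), "hard core")
  # R and C++ energies agree on random self-avoiding chains
  set.seed(20)
  for (conf in rejection_saw(5, 8)) {
    expect_equal(total_energy(conf, square_well_model(n = 8)),
                 chainscales:::cpp_total_energy(conf$coords, b, 1.6 * b))
  }
})

test_that("proposed moves preserve bonds exactly and pivot identity is a no-op", {
  set.seed(21)
  conf <- rejection_saw(1, 12)[[1]]
  for (mt in c("crankshaft", "reptation", "endpoint", "pivot")) {
    for (k in 1:25) {
      cand <- propose_move(conf, mt)
      expect_equal(attr(cand, "move_type"), mt)
      expect_equal(n_monomers(cand), 12L)
      expect_lt(max(abs(bond_lengths(cand) - conf$b)), 1e-9 * conf$b)
    }
  }
  # accepted long runs do not drift the bond lengths
  model <- square_well_model(n = 20)
  run <- run_infinite_temperature(model, sweeps = 600, burnin = 100,
                                  snapshot_stride = 100)
  snaps <- run$snapshots
  for (s in seq_len(dim(snaps)[3])) {
    d <- sqrt(rowSums(diff(t(snaps[, , s]))^2))
    expect_lt(max(abs(d - model$sigma)), 1e-9 * model$sigma)
  }
})

test_that("metropolis step rejects overlaps and always takes downhill moves", {
  set.seed(22)
  model <- square_well_model(n = 8)
  conf <- rejection_saw(1, 8)[[1]]
  e <- total_energy(conf, model)
  for (k in 1:30) {
    st <- metropolis_step(conf, model, reduced_T = Inf)
    expect_false(chainscales:::cpp_has_overlap(st$conf$coords, model$sigma))
    if (st$accepted) {
      conf <- st$conf
      e <- st$energy
    } else {
      expect_equal(st$energy, e)
    }
  }
  expect_error(metropolis_step(conf, model, reduced_T = 0), "reduced_T")
})

test_that("engine energy bookkeeping matches full recomputation", {
  set.seed(23)
  model <- square_well_model(n = 20)
  run <- chainscales:::cpp_run_mc(straight_chain(20)$coords, model$sigma,
                                  model$R_att, 0.4, 400L, 100L, 1L, 1L)
  k <- dim(run$snapshots)[3]
  expect_equal(length(run$energies), k) # aligned sampling
  for (s in seq(1, k, by = 37)) {
    conf <- conformation(t(run$snapshots[, , s]), b = model$sigma)
    expect_equal(run$energies[s], total_energy(conf, model))
  }
  expect_equal(run$final_energy,
               total_energy(conformation(run$final, b = model$sigma), model))
})

test_that("short-chain sampling reproduces Boltzmann statistics", {
  # detailed-balance smoke test: n = 4 tangent chain at kT/eps = 0.5;
  # compare the engine's energy-level frequencies against exact
  # reweighting of rejection-sampled (uniform) self-avoiding chains
  set.seed(24)
  model <- square_well_model(n = 4)
  Tred <- 0.5
  confs <- rejection_saw(4000, 4)
  e_flat <- vapply(confs, total_energy, numeric(1), model = model)
  w <- exp(-e_flat / Tred)
  p_exact <- tapply(w, factor(e_flat, levels = -3:0), sum)
  p_exact[is.na(p_exact)] <- 0
  p_exact <- p_exact / sum(p_exact)
  run <- chainscales:::cpp_run_mc(straight_chain(4)$coords, model$sigma,
                                  model$R_att, Tred, 60000L, 5000L, 1L, 0L)
  p_mc <- table(factor(run$energies, levels = -3:0)) / length(run$energies)
  expect_lt(max(abs(as.numeric(p_mc) - as.numeric(p_exact))), 0.02)
})

test_that("infinite-temperature sampling is athermal and SAW-like", {
  set.seed(25)
  msd <- vapply(c(20L, 40L, 80L), function(n) {
    model <- square_well_model(n = n)
    run <- run_infinite_temperature(model, sweeps = 4000, burnin = 1000,
                                    snapshot_stride = 5)
    snaps <- run$snapshots
    # every snapshot honors the hard core
    for (s in seq(1, dim(snaps)[3], by = 100))
      expect_false(chainscales:::cpp_has_overlap(t(snaps[, , s]),
                                                 model$sigma))
    mean(vapply(seq_len(dim(snaps)[3]), function(s)
      sum((snaps[, n, s] - snaps[, 1, s])^2), numeric(1)))
  }, numeric(1))
  # swelling: mean squared end-to-end grows faster than chain length
  expect_gt(msd[2] / msd[1], 2)
  expect_gt(msd[3] / msd[2], 2)
  # hard-sphere bound on the bending angles
  set.seed(26)
  model <- square_well_model(80)
  run <- run_infinite_temperature(model, sweeps = 2000, burnin = 500,
                                  snapshot_stride = 10)
  r <- snapshot_local_radii(run$snapshots, model$sigma)
  expect_gte(min(r), model$sigma / sqrt(3) - 1e-9)
})

test_that("replica exchange swaps are exact at equal temperatures", {
  set.seed(27)
  model <- square_well_model(n = 16)
  res <- chainscales:::cpp_run_re(straight_chain(16)$coords, model$sigma,
                                  model$R_att, c(0.7, 0.7), 400L, 100L, 5L,
                                  5L, integer(0), 0L)
  expect_equal(res$swap_acceptance, 1) # delta beta = 0
  ladder <- replica_ladder(1)
  expect_true(all(diff(ladder) > 0))
  expect_equal(ladder[1:3], c(0.3, 0.32, 0.34))
  expect_equal(length(replica_ladder(4)), 36)
})

test_that("WHAM degenerates to the single-histogram fluctuation estimator", {
  set.seed(28)
  model <- square_well_model(n = 16)
  run <- chainscales:::cpp_run_mc(straight_chain(16)$coords, model$sigma,
                                  model$R_att, 0.8, 20000L, 4000L, 4L, 0L)
  direct <- fluctuation_cv(run$energies, 0.8, 16)
  wh <- wham_specific_heat(list(run$energies), T_grid = 0.8,
                           temperatures = 0.8, n = 16)
  expect_equal(wh$cv, direct, tolerance = 1e-6)
})

test_that("WHAM recovers the closed-form two-level specific heat", {
  set.seed(29)
  g0 <- 5; g1 <- 1
  temps <- c(0.3, 0.45, 0.7, 1, 1.5)
  traces <- lapply(temps, function(tt) two_level_sample(20000, tt, g0, g1))
  grid <- seq(0.25, 1.6, by = 0.05)
  wh <- wham_specific_heat(traces, T_grid = grid, temperatures = temps,
                           n = 1)
  exact <- two_level_cv(grid, g0, g1)
  expect_lt(max(abs(wh$cv - exact)), 0.03)
  # the density of states ratio is recovered
  lg <- attr(wh, "log_g")
  expect_equal(lg$log_g[lg$E == -1] - lg$log_g[lg$E == 0], log(g1 / g0),
               tolerance = 0.05)
  # the peak sits where the closed form puts it
  expect_equal(grid[which.max(wh$cv)], grid[which.max(exact)],
               tolerance = 0.05 + 1e-9)
})

test_that("energy autocorrelation time is sane", {
  set.seed(30)
  white <- rnorm(5000)
  expect_lt(energy_autocorrelation_time(white), 1.5)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 5000))
  expect_gt(energy_autocorrelation_time(ar), 5)
  expect_equal(energy_autocorrelation_time(rep(2, 100)), 1)
})
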