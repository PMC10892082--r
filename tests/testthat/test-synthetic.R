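test_that("fixed-bond walks have exact bonds and the right angle statistics", {
  set.seed(10)
  w <- random_walk(10, d = 3, b = 3.81)
  expect_true(all(abs(bond_lengths(w) - 3.81) < 1e-12))
  w2 <- random_walk(5, d = 2)
  expect_true(all(w2$coords[, 3] == 0))
  expect_error(random_walk(2, d = 4), "higher dimensions")
  b4 <- random_walk_batch(100, 2, d = 4, b = 1)
  expect_equal(dim(b4), c(100, 12))
  # all steps unit length in 4D
  step1 <- b4[, 5:8] - b4[, 1:4]
  expect_true(all(abs(sqrt(rowSums(step1^2)) - 1) < 1e-12))

  # theta distributions against the analytic CDF (distribution test)
  n <- 1e5
  for (d in 2:3) {
    wb <- random_walk_batch(n, 2, d = d, b = 3.81)
    dd <- attr(wb, "d")
    u <- wb[, (dd + 1):(2 * dd)] - wb[, 1:dd]
    v <- wb[, (2 * dd + 1):(3 * dd)] - wb[, (dd + 1):(2 * dd)]
    th <- acos(pmin(1, pmax(-1, -rowSums(u * v) /
                              (sqrt(rowSums(u * u) * rowSums(v * v)))))) *
      180 / pi
    ks <- max(abs(ecdf(th)(seq(1, 179, by = 0.5)) -
                    p_theta_cdf(seq(1, 179, by = 0.5), d)))
    expect_lt(ks, 0.01)
  }
})

test_that("constrained walks are planar for three points, 3D for the fourth", {
  set.seed(12)
  cw <- constrained_walk_batch(2000, b = 3.81)
  expect_true(all(cw[, c(3, 6, 9)] == 0)) # first three points in z = 0
  expect_gt(sd(cw[, 12]), 1) # fourth point leaves the plane
  for (k in c(1, 500)) {
    p <- matrix(cw[k, ], 4, 3, byrow = TRUE)
    expect_true(all(abs(sqrt(rowSums(diff(p)^2)) - 3.81) < 1e-9))
  }
  one <- constrained_random_walk()
  expect_s3_class(one, "conformation")
  expect_equal(n_monomers(one), 4L)
})

test_that("uniform ball points have the cubic radial law and vanishing mean", {
  set.seed(13)
  p <- uniform_ball_points(2e4, radius = 2)
  r <- sqrt(rowSums(p^2))
  expect_true(all(r <= 2))
  grid <- seq(0.1, 1.9, by = 0.1)
  expect_lt(max(abs(ecdf(r)(grid) - (grid / 2)^3)), 0.015)
  expect_lt(max(abs(colMeans(p))), 0.05)
  expect_error(uniform_ball_points(2), "at least 3")
})

test_that("self-avoiding segments respect the tangent hard core", {
  set.seed(14)
  sa <- self_avoiding_walk_batch(5000, 2, b = 3.81)
  # theta >= 60 for every two-step tangent walk
  u <- sa[, 4:6] - sa[, 1:3]
  v <- sa[, 7:9] - sa[, 4:6]
  th <- acos(pmin(1, pmax(-1, -rowSums(u * v) / 3.81^2))) * 180 / pi
  expect_gte(min(th), 60 - 1e-6)
  expect_lt(attr(sa, "acceptance"), 1)
  expect_gt(attr(sa, "acceptance"), 0.5) # P(theta >= 60) = 0.75 for sin theta
  seg <- self_avoiding_segment(5)
  expect_true(all(abs(bond_lengths(seg) - 3.81) < 1e-12))
  expect_false(chainscales:::cpp_has_overlap(seg$coords, 3.81))
})

test_that("ideal helix hits the canonical C-alpha geometry", {
  h <- ideal_alpha_helix(30)
  expect_lt(abs(h$b - 3.81), 0.05)
  th <- theta_mu_map(h)$theta
  expect_true(all(abs(th - 92) < 2.5)) # helix bending angle ~ 92 degrees
  expect_true(all(h$labels == "alpha"))
  rec <- nearest_nonlocal_contact(h)
  expect_equal(as.integer(names(which.max(table(rec$separation)))), 3L)
  expect_error(ideal_alpha_helix(30, rise = 3), "0.05 A from target")
})

test_that("ideal sheets give 120-degree strands and the expected contact pattern", {
  sheet <- ideal_beta_sheet(strand_lengths = c(8L, 8L))
  th <- chainscales:::chain_thetas(sheet$coords)
  strand_interior <- sheet$labels[2:(n_monomers(sheet) - 1)] == "beta" &
    sheet$labels[1:(n_monomers(sheet) - 2)] == "beta" &
    sheet$labels[3:n_monomers(sheet)] == "beta"
  expect_true(all(abs(th[strand_interior] - 120) < 0.5))
  expect_true(all(abs(bond_lengths(sheet) - 3.81) < 1e-9))
  cm <- contact_map(sheet)
  beta_near <- cm[cm$near & sheet$labels[cm$i] == "beta" &
                    sheet$labels[cm$j] == "beta", ]
  expect_gt(nrow(beta_near), 0)
  expect_lte(diff(range(beta_near$i + beta_near$j)), 2) # antiparallel: i+j const
  par <- ideal_beta_sheet(strand_lengths = c(8L, 8L), topology = "parallel")
  cmp <- contact_map(par)
  pn <- cmp[cmp$near & par$labels[cmp$i] == "beta" &
              par$labels[cmp$j] == "beta" & cmp$j > cmp$i, ]
  expect_true(all(pn$j - pn$i >= 4)) # parallel: off-diagonal band
  expect_lte(diff(range(pn$j - pn$i)), 2)
})

test_that("composed chains keep segment geometry and ground-truth labels", {
  set.seed(15)
  h <- ideal_alpha_helix(10)
  s <- ideal_beta_sheet(strand_lengths = c(6L, 6L))
  mix <- compose_labeled_chain(list(h, s))
  expect_equal(n_monomers(mix), n_monomers(h) + n_monomers(s))
  expect_equal(mix$labels, c(h$labels, s$labels))
  # helix block preserved exactly (jitter 0)
  expect_equal(mix$coords[1:10, ], h$coords, ignore_attr = TRUE)
  # sheet block preserved up to the rigid shift
  shift <- mix$coords[11, ] - s$coords[1, ]
  expect_lt(max(abs(sweep(mix$coords[11:nrow(mix$coords), ], 2, shift) -
                      s$coords)), 1e-9)
  jit <- compose_labeled_chain(list(h, s), jitter_sd = 0.1)
  expect_false(jit$fixed_bonds)
  expect_gt(max(abs(jit$coords[1:10, ] - h$coords)), 0)
})
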