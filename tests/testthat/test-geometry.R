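test_that("bond-bending angle matches elementary geometry", {
  expect_equal(bond_bending_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 180)
  expect_equal(bond_bending_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 90)
  expect_equal(bond_bending_angle(c(0, 0, 0), c(1, 0, 0),
                                  c(0.5, sqrt(3) / 2, 0)), 60)
  expect_error(bond_bending_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "coincident")
})

test_that("dihedral angle follows the right-handed binormal convention", {
  # planar trans zigzag -> 180
  expect_equal(abs(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1.5, 0.87, 0),
                                  c(2.5, 0.87, 0))), 180)
  # cis-planar quartet (4th point folded back in plane) -> 0
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1.5, 0.87, 0),
                              c(0.5, 0.87, 0)), 0)
  # 90-degree rotation out of plane about the p2-p3 axis; verify the sign
  # with an independent cross-product oracle
  p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  p4 <- c(1, 0, 1)
  mu <- dihedral_angle(p1, p2, p3, p4)
  expect_equal(abs(mu), 90)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cr <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  expect_equal(sign(mu), sign(sum(cr * b2)))
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")
})

test_that("triplet circumradius equals R = abc/4A and flags collinearity", {
  expect_equal(circumradius_triplet(c(0, 0, 0), c(1, 0, 0),
                                    c(0.5, sqrt(3) / 2, 0))$R,
               1 / sqrt(3), tolerance = 1e-12)
  col <- circumradius_triplet(c(0, 0, 0), c(1, 0, 0), c(2.5, 0, 0))
  expect_true(is.infinite(col$R))
  expect_identical(col$X, 0)
  expect_error(circumradius_triplet(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)),
               "coincident")
})

test_that("circumradius of isoceles triplets reproduces the local-radius closed form", {
  b <- 3.81
  for (theta in seq(1, 179, by = 1)) {
    th <- theta * pi / 180
    p1 <- c(b * sin(th / 2), b * cos(th / 2), 0)
    p2 <- c(0, 0, 0)
    p3 <- c(-b * sin(th / 2), b * cos(th / 2), 0)
    expect_equal(circumradius_triplet(p1, p2, p3)$R,
                 local_radius_from_theta(theta, b),
                 tolerance = 1e-9)
  }
  # spot value: two 3.81-A bonds at 92 degrees
  expect_equal(local_radius_from_theta(92, 3.81), 3.81 / (2 * cos(46 * pi / 180)),
               tolerance = 1e-12)
  expect_true(is.infinite(local_radius_from_theta(180, 3.81)))
  expect_error(local_radius_from_theta(181, 3.81), "theta")
})

test_that("circumsphere radius solves the equidistant-center system", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  rs <- circumsphere_radius_quartet(tet[1, ], tet[2, ], tet[3, ], tet[4, ])
  expect_equal(rs$R, sqrt(3 / 8), tolerance = 1e-12)
  cop <- circumsphere_radius_quartet(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                     c(1, 1, 0))
  expect_true(is.infinite(cop$R))
  expect_identical(cop$X, 0)
  # residual check on random non-degenerate quartets
  set.seed(42)
  for (k in 1:50) {
    pts <- matrix(rnorm(12, sd = 3), 4, 3)
    rs <- circumsphere_radius_quartet(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    if (!is.finite(rs$R)) next
    d <- sqrt(rowSums(sweep(pts, 2, rs$center)^2))
    expect_lt(max(abs(d - rs$R)) / rs$R, 1e-9)
  }
})

test_that("radii are rigid-motion invariant and scale linearly", {
  set.seed(7)
  for (k in 1:20) {
    pts <- matrix(rnorm(12, sd = 2), 4, 3)
    R3 <- circumradius_triplet(pts[1, ], pts[2, ], pts[3, ])$R
    R4 <- circumsphere_radius_quartet(pts[1, ], pts[2, ], pts[3, ], pts[4, ])$R
    rot <- random_rotation_oracle()
    tr <- rnorm(3, sd = 10)
    q <- sweep(pts %*% t(rot), 2, tr, "+")
    expect_equal(circumradius_triplet(q[1, ], q[2, ], q[3, ])$R, R3,
                 tolerance = 1e-9)
    expect_equal(circumsphere_radius_quartet(q[1, ], q[2, ], q[3, ],
                                             q[4, ])$R, R4,
                 tolerance = 1e-9)
    s <- pts * 2.5
    expect_equal(circumradius_triplet(s[1, ], s[2, ], s[3, ])$R, 2.5 * R3,
                 tolerance = 1e-9)
    expect_equal(circumsphere_radius_quartet(s[1, ], s[2, ], s[3, ],
                                             s[4, ])$R, 2.5 * R4,
                 tolerance = 1e-9)
  }
})

test_that("theta-mu map covers interior quartets with documented indexing", {
  set.seed(1)
  w <- random_walk(3)
  m <- theta_mu_map(w)
  expect_equal(nrow(m), 1L)
  w2 <- random_walk(9)
  m2 <- theta_mu_map(w2)
  expect_equal(nrow(m2), 10 - 3)
  # theta column matches the scalar kernel at the quartet's interior vertex
  expect_equal(m2$theta[4],
               bond_bending_angle(w2$coords[4, ], w2$coords[5, ],
                                  w2$coords[6, ]))
  expect_equal(m2$mu[4],
               dihedral_angle(w2$coords[4, ], w2$coords[5, ], w2$coords[6, ],
                              w2$coords[7, ]))
  # straight chain: all theta 180, dihedrals undefined
  s <- straight_chain(6)
  ms <- theta_mu_map(s)
  expect_true(all(ms$theta == 180))
  expect_true(all(is.na(ms$mu)))
})

test_that("nearest non-local contacts match a brute-force scan", {
  set.seed(11)
  for (n in c(4L, 7L, 12L, 20L)) {
    conf <- rejection_saw(1, n)[[1]]
    rec <- nearest_nonlocal_contact(conf)
    oracle <- brute_nearest(conf$coords)
    expect_equal(rec$j, as.integer(oracle[, 1]))
    expect_equal(rec$distance, oracle[, 2], tolerance = 1e-12)
  }
  # straight chain: interior beads find the partner at separation 3
  s <- straight_chain(10)
  rec <- nearest_nonlocal_contact(s)
  expect_true(all(rec$separation == 3))
  expect_true(all(abs(rec$distance - 3 * 3.81) < 1e-9))
  # n = 4: single admissible pair for both ends
  r4 <- nearest_nonlocal_contact(straight_chain(4))
  expect_equal(r4$j[1], 4L)
  expect_equal(r4$j[4], 1L)
  expect_warning(nearest_nonlocal_contact(straight_chain(3)), "too short")
})

test_that("contact map near flag uses the 6-angstrom threshold", {
  s <- straight_chain(10)
  cm <- contact_map(s)
  expect_true(all(!cm$near)) # 11.43 > 6
  h <- ideal_alpha_helix(30)
  cmh <- contact_map(h)
  expect_true(all(cmh$near)) # ~5.05 < 6
})
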