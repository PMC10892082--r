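# minimal DSSP-format writer for fixtures (header + per-residue rows with
# the secondary-structure code in column 17)
write_fake_dssp <- function(path, ss, chain = "A", resno = seq_along(ss)) {
  hdr <- c("==== Secondary Structure Definition, fixture ====",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  rows <- sprintf("%5d%5d %s %s  %s", seq_along(ss), resno, chain, "G", ss)
  writeLines(c(hdr, rows), path)
  path
}

test_that("CA-only PDB files round-trip through the reader", {
  set.seed(40)
  conf <- rejection_saw(1, 15)[[1]]
  f <- tempfile(fileext = ".pdb")
  write_ca_pdb(conf, f, chain = "B")
  back <- read_calpha_trace(f, "B")
  expect_lt(max(abs(back$coords - conf$coords)), 1e-3) # fixed-width precision
  expect_error(read_calpha_trace(f, "Z"), "not found")
})

test_that("chain breaks are rejected or split per configuration", {
  b <- 3.81
  coords <- rbind(cbind(0:4 * b, 0, 0), cbind(0:6 * b + 40, 10, 0))
  conf <- conformation(coords, b = b, fixed_bonds = FALSE)
  f <- tempfile(fileext = ".pdb")
  write_ca_pdb(conf, f)
  expect_error(read_calpha_trace(f, "A"), "chain break")
  kept <- read_calpha_trace(f, "A", on_break = "split")
  expect_equal(n_monomers(kept), 7L) # longest contiguous piece
})

test_that("omega classification separates trans, cis and breaks", {
  b_trans <- 3.81
  b_cis <- 2.95
  coords <- rbind(c(0, 0, 0), c(b_trans, 0, 0), c(b_trans, b_cis, 0),
                  c(b_trans + 20, b_cis, 0))
  conf <- conformation(coords, b = b_trans, fixed_bonds = FALSE)
  expect_equal(classify_omega(conf), c("trans", "cis", "unknown"))
  # full-backbone omega: synthetic planar peptide with omega = 180 is trans
  lines <- c(
    sprintf("ATOM  %5d  N   GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           N",
            1, 1, 0, 1.4, 0),
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            2, 1, 0, 0, 0),
    sprintf("ATOM  %5d  C   GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            3, 1, 1.5, 0, 0),
    sprintf("ATOM  %5d  N   GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           N",
            4, 2, 2.2, -1.1, 0),
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            5, 2, 3.6, -1.2, 0),
    sprintf("ATOM  %5d  C   GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            6, 2, 4.3, -2.5, 0),
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  om <- classify_omega_backbone(f, "A")
  # CA(1), C(1), N(2), CA(2) all in z = 0 with CA atoms on opposite sides
  expect_equal(abs(om$omega), 180, tolerance = 1e-6)
  expect_equal(om$omega_class, "trans")
})

test_that("DSSP parsing and class mapping follow the three-class scheme", {
  f <- tempfile(fileext = ".dssp")
  write_fake_dssp(f, c("H", "H", "H", "E", "E", " ", "T", "G"))
  d <- read_dssp(f)
  expect_equal(nrow(d), 8L)
  cls <- assign_structure_class(d, chain = "A")
  expect_equal(cls, c("alpha", "alpha", "alpha", "beta", "beta", "loop",
                      "loop", "loop"))
  # configurable helix codes
  cls2 <- assign_structure_class(d, helix_codes = c("H", "G"))
  expect_equal(cls2[8], "alpha")
  # all-H and all-E degenerate files
  fh <- write_fake_dssp(tempfile(), rep("H", 5))
  expect_true(all(assign_structure_class(fh) == "alpha"))
  fe <- write_fake_dssp(tempfile(), rep("E", 5))
  expect_true(all(assign_structure_class(fe) == "beta"))
  # residue-count mismatch against a trace errors
  expect_error(assign_structure_class(d, conf = straight_chain(5)),
               "does not match")
})

test_that("the angle-window heuristic labels ideal fixtures correctly", {
  h <- ideal_alpha_helix(20)
  cls <- assign_structure_class_heuristic(h)
  expect_equal(attr(cls, "method"), "theta-mu-heuristic")
  expect_true(all(cls[3:17] == "alpha")) # interior residues
  sheet <- ideal_beta_sheet(strand_lengths = c(10L, 10L))
  cls_s <- assign_structure_class_heuristic(sheet)
  interior_strand <- which(sheet$labels == "beta")
  interior_strand <- interior_strand[interior_strand >= 3 &
                                       interior_strand <= 8]
  expect_true(all(cls_s[interior_strand] == "beta"))
})

test_that("per-class statistics use pure triplets and conserve pooled data", {
  set.seed(41)
  h <- ideal_alpha_helix(30)
  sheet <- ideal_beta_sheet(strand_lengths = c(8L, 8L))
  stats <- suppressWarnings(per_class_statistics(list(h, sheet)))
  expect_true(all(c("alpha", "beta") %in% stats$class))
  a <- stats[stats$class == "alpha", ]
  expect_equal(a$local_mode, local_radius_from_theta(
    theta_mu_map(h)$theta[1], h$b), tolerance = 0.05)
  expect_equal(a$nonlocal_mode, 5.06, tolerance = 0.05)
  # single-class chain: other classes warned and omitted
  expect_warning(per_class_statistics(h, classes = c("alpha", "beta")),
                 "absent")
  # permuting labels changes class rows, not the pooled statistics
  mix <- compose_labeled_chain(list(ideal_alpha_helix(12),
                                    ideal_beta_sheet(strand_lengths =
                                                       c(6L, 6L))))
  perm <- conformation(mix$coords, b = mix$b,
                       labels = rev(mix$labels), fixed_bonds = FALSE)
  pooled1 <- sort(contact_distances(mix))
  pooled2 <- sort(contact_distances(perm))
  expect_equal(pooled1, pooled2)
  # the pure-triplet filter only counts label-homogeneous triplets
  n_alpha_pure <- sum(vapply(seq_len(n_monomers(mix) - 2), function(i)
    all(mix$labels[i:(i + 2)] == "alpha"), logical(1)))
  expect_equal(length(local_radii(mix, pure_class = "alpha")), n_alpha_pure)
})

test_that("scaled profiles sit near one for matched scales", {
  h <- ideal_alpha_helix(30)
  sc <- per_class_statistics(h, classes = "alpha")
  prof <- scaled_profile(h, list(alpha = c(sc$local_mode, sc$nonlocal_mode)))
  expect_lt(max(abs(prof$scaled_local - 1), na.rm = TRUE), 0.05)
  expect_lt(max(abs(prof$scaled_nonlocal - 1)), 0.05)
  # unit scales are a passthrough
  prof1 <- scaled_profile(h, list(alpha = c(1, 1)))
  rec <- nearest_nonlocal_contact(h)
  expect_equal(prof1$scaled_nonlocal, rec$distance)
  # straight chain: infinite scaled local radius, flagged
  s <- straight_chain(8)
  profs <- scaled_profile(s, list(none = c(1, 1)))
  expect_true(all(profs$straight[2:7]))
  # missing scale errors by class name
  expect_error(scaled_profile(h, list(beta = c(1, 1))), "alpha")
})

test_that("residue geometry CSV has one row per residue", {
  h <- ideal_alpha_helix(12)
  f <- tempfile(fileext = ".csv")
  df <- write_residue_geometry_csv(h, f)
  expect_equal(nrow(df), 12L)
  back <- read.csv(f)
  expect_equal(names(back),
               c("i", "class", "omega_class", "theta", "mu", "local_radius",
                 "contact_j", "contact_distance"))
  expect_true(all(back$omega_class[-1] == "trans"))
})
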