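#' Read a C-alpha trace from a PDB file
#'
#' Extracts the ordered C-alpha coordinates of one chain via bio3d.  Only
#' the first model of multi-model files is used, and where alternate
#' locations exist the highest-occupancy one is kept.  Consecutive
#' C-alpha distances are screened: the canonical trans peptide gives about
#' 3.81 angstrom and the rare cis peptide about 2.95; a distance above
#' `break_tol` (default 4.5 angstrom) is a chain break, handled per
#' `on_break`.
#'
#' @param path PDB-format file.
#' @param chain one-letter chain identifier.
#' @param on_break `"error"` rejects chains with breaks, `"split"` returns
#'   the longest contiguous piece.
#' @param break_tol chain-break distance threshold (angstrom).
#' @param b nominal bond length recorded on the conformation.
#' @return a `conformation` (with `fixed_bonds = FALSE`: real chains have
#'   variable bonds).
#' @export
read_calpha_trace <- function(path, chain, on_break = c("error", "split"),
                              break_tol = 4.5, b = 3.81) {
  on_break <- match.arg(on_break)
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_calpha_trace() needs the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$chain == chain & at$elety == "CA" &
             at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!nrow(at)) stop("chain '", chain, "' not found in ", path)
  # altloc: keep highest occupancy per residue
  key <- paste(at$resno, at$insert)
  if (anyDuplicated(key)) {
    ord <- order(key, -replace(at$o, is.na(at$o), 1))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$resno, at$insert)), , drop = FALSE]
  }
  at <- at[order(at$resno), , drop = FALSE]
  coords <- as.matrix(at[, c("x", "y", "z")])
  rownames(coords) <- NULL
  d <- bond_lengths_matrix(coords)
  brk <- which(d > break_tol)
  if (length(brk)) {
    if (on_break == "error")
      stop("chain break(s) in ", path, " chain ", chain,
           " at position(s) ", paste(brk, collapse = ", "),
           " (C-alpha gap > ", break_tol, " A)")
    # keep the longest contiguous segment
    bounds <- c(0, brk, nrow(coords))
    lens <- diff(bounds)
    k <- which.max(lens)
    coords <- coords[(bounds[k] + 1):bounds[k + 1], , drop = FALSE]
  }
  if (nrow(coords) < 2) stop("fewer than 2 C-alpha atoms after filtering")
  conformation(coords, b = b, fixed_bonds = FALSE)
}

#' Classify peptide bonds as trans or cis
#'
#' Proxy classification from consecutive C-alpha distances: the trans
#' peptide places consecutive C-alpha atoms near 3.81 angstrom and the
#' cis peptide near 2.95, so distances below `cis_tol` (3.4 angstrom, the
#' midpoint of the two populations) are called cis.  Distances above
#' `break_tol` are `"unknown"` (chain break, not a peptide geometry).
#'
#' @param conf a `conformation` (C-alpha trace).
#' @param cis_tol cis/trans distance threshold (angstrom).
#' @param break_tol chain-break threshold (angstrom).
#' @return character vector of length n - 1 over consecutive bonds, values
#'   `"trans"`, `"cis"` or `"unknown"`.
#' @export
classify_omega <- function(conf, cis_tol = 3.4, break_tol = 4.5) {
  stopifnot(inherits(conf, "conformation"))
  d <- bond_lengths(conf)
  ifelse(d > break_tol, "unknown", ifelse(d < cis_tol, "cis", "trans"))
}

#' Classify omega from a full backbone
#'
#' When N and C atoms are available the true Ramachandran omega dihedral
#' CA(i)-C(i)-N(i+1)-CA(i+1) is computed and |omega| <= 90 degrees is
#' called cis (canonical trans has |omega| near 180).
#'
#' @param path PDB file with full backbone atoms.
#' @param chain chain identifier.
#' @return data.frame with `resno`, `omega` (degrees) and `omega_class`
#'   per consecutive residue pair.
#' @export
classify_omega_backbone <- function(path, chain) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("classify_omega_backbone() needs the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$chain == chain & at$type == "ATOM", , drop = FALSE]
  res <- sort(unique(at$resno))
  get_atom <- function(rn, name) {
    row <- at[at$resno == rn & at$elety == name, , drop = FALSE]
    if (!nrow(row)) return(NULL)
    as.numeric(row[1, c("x", "y", "z")])
  }
  out <- data.frame(resno = integer(), omega = numeric(),
                    omega_class = character())
  for (k in seq_len(length(res) - 1)) {
    ca1 <- get_atom(res[k], "CA"); c1 <- get_atom(res[k], "C")
    n2 <- get_atom(res[k + 1], "N"); ca2 <- get_atom(res[k + 1], "CA")
    if (is.null(ca1) || is.null(c1) || is.null(n2) || is.null(ca2))
      stop("missing backbone atoms at residue ", res[k])
    om <- dihedral_angle(ca1, c1, n2, ca2)
    out <- rbind(out, data.frame(
      resno = res[k], omega = om,
      omega_class = if (abs(om) <= 90) "cis" else "trans"))
  }
  out
}

#' Parse a DSSP output file
#'
#' Reads the per-residue table of classic DSSP output (the block after the
#' `#  RESIDUE AA STRUCTURE` header; secondary-structure code in column
#' 17).  Residues DSSP marks as chain breaks (`!`) are skipped.
#'
#' @param path DSSP output file.
#' @return data.frame with `resno`, `chain`, `aa`, `ss`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not a DSSP output file: ", path)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]
  data.frame(resno = as.integer(trimws(substr(body, 6, 10))),
             chain = substr(body, 12, 12),
             aa = aa[keep],
             ss = substr(body, 17, 17))
}

#' Per-residue structural class from DSSP output
#'
#' Maps DSSP codes to the three-class scheme: helix codes (`"H"` by
#' default; optionally the 3-10 and pi codes G and I) to `"alpha"`, `"E"`
#' to `"beta"`, everything else to `"loop"`.
#'
#' @param dssp path to a DSSP file or a data.frame from [read_dssp()].
#' @param chain chain to select.
#' @param conf optional `conformation` to check the residue count against
#'   (mismatch is an error).
#' @param helix_codes DSSP codes mapped to `"alpha"`.
#' @return character vector of classes, one per residue.
#' @export
assign_structure_class <- function(dssp, chain = NULL, conf = NULL,
                                   helix_codes = "H") {
  if (is.character(dssp) && length(dssp) == 1) dssp <- read_dssp(dssp)
  if (!is.null(chain)) dssp <- dssp[dssp$chain == chain, , drop = FALSE]
  if (!nrow(dssp)) stop("no DSSP residues", if (!is.null(chain))
    paste0(" for chain ", chain))
  cls <- ifelse(dssp$ss %in% helix_codes, "alpha",
                ifelse(dssp$ss == "E", "beta", "loop"))
  if (!is.null(conf) && length(cls) != n_monomers(conf))
    stop("DSSP residue count (", length(cls),
         ") does not match the trace (", n_monomers(conf), ")")
  cls
}

#' Heuristic structural classes from backbone angles
#'
#' A fallback used when no DSSP output is available; NOT a DSSP
#' reimplementation and flagged as such in its output attribute.  Each
#' interior residue is classified from its bending angle theta and the
#' dihedral mu of the quartet starting at the previous residue: theta in
#' [85, 100] with mu in [30, 80] is alpha-like (the ideal helix sits at
#' theta ~ 92, mu ~ 50); theta in [100, 145] with |mu| >= 140 is
#' beta-like (the ideal strand sits at theta = 120, mu = 180); all else,
#' including chain ends, is loop.
#'
#' @param conf a `conformation`.
#' @return character vector of classes with attribute
#'   `"method" = "theta-mu-heuristic"`.
#' @export
assign_structure_class_heuristic <- function(conf) {
  n <- n_monomers(conf)
  cls <- rep("loop", n)
  th <- chain_thetas(conf$coords) # vertices 2..n-1
  mu <- chain_dihedrals(conf$coords) # quartets 1..n-3
  for (i in 2:(n - 1)) {
    t_i <- th[i - 1]
    m_i <- if (i >= 2 && i <= n - 2) mu[i - 1] else NA_real_
    if (is.na(m_i)) next
    if (t_i >= 85 && t_i <= 100 && m_i >= 30 && m_i <= 80)
      cls[i] <- "alpha"
    else if (t_i >= 100 && t_i <= 145 && abs(m_i) >= 140)
      cls[i] <- "beta"
  }
  attr(cls, "method") <- "theta-mu-heuristic"
  cls
}

#' Per-class length-scale summary
#'
#' Characteristic local and non-local length scales per structural class
#' over a set of labeled conformations, the per-class counterpart of
#' [length_scale_modes()]: local-radius modes use only pure triplets (all
#' three monomers in the same class), non-local modes use the monomers of
#' the class.  Absent classes are omitted with a warning.
#'
#' @param confs labeled `conformation` or list of them.
#' @param classes classes to report.
#' @inheritParams length_scale_modes
#' @return data.frame with one row per present class: `class`,
#'   `local_mode`, `nonlocal_mode`, `n_triplets`, `n_monomers`.
#' @export
per_class_statistics <- function(confs, classes = c("alpha", "beta", "loop"),
                                 estimator = c("inverse", "direct"),
                                 local_bin = 0.02, nonlocal_bin = 0.04,
                                 local_xbin = 0.004, nonlocal_xbin = 0.001,
                                 min_sep = 3L) {
  estimator <- match.arg(estimator)
  if (inherits(confs, "conformation")) confs <- list(confs)
  present <- unique(unlist(lapply(confs, `[[`, "labels")))
  out <- NULL
  for (cl in classes) {
    if (!cl %in% present) {
      warning("class '", cl, "' absent; omitted")
      next
    }
    r <- local_radii(confs, pure_class = cl)
    d <- contact_distances(confs, min_sep = min_sep, class_filter = cl)
    row <- data.frame(class = cl,
                      local_mode = if (any(is.finite(r)))
                        scale_mode(r, estimator, local_bin, local_xbin)
                      else NA_real_,
                      nonlocal_mode = if (length(d))
                        scale_mode(d, estimator, nonlocal_bin, nonlocal_xbin)
                      else NA_real_,
                      n_triplets = length(r), n_monomers = length(d))
    out <- rbind(out, row)
  }
  if (is.null(out)) stop("none of the requested classes are present")
  out
}

#' Per-residue geometry CSV
#'
#' Writes one row per residue: index, class label, omega class of the
#' preceding bond, theta, mu, local radius, nearest non-local partner and
#' distance.
#'
#' @param conf a `conformation`.
#' @param path output path.
#' @param min_sep minimum contact separation.
#' @export
write_residue_geometry_csv <- function(conf, path, min_sep = 3L) {
  n <- n_monomers(conf)
  th <- c(NA, chain_thetas(conf$coords), NA)
  mu <- c(NA, chain_dihedrals(conf$coords), NA, NA)
  r <- c(NA, local_radius_from_theta(chain_thetas(conf$coords), conf$b), NA)
  om <- c(NA, classify_omega(conf))
  ct <- nearest_nonlocal_contact(conf, min_sep = min_sep)
  df <- data.frame(i = seq_len(n),
                   class = if (is.null(conf$labels)) "none" else conf$labels,
                   omega_class = om, theta = th, mu = mu, local_radius = r,
                   contact_j = ct$j, contact_distance = ct$distance)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
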