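#' Chain conformation objects
#'
#' A `conformation` is an ordered sequence of n points in 3D (angstrom)
#' with a nominal bond length `b` and optional per-monomer structural class
#' labels.  It is the universal input to all geometry operations in the
#' package: angle maps, circumradius statistics, contact maps and length
#' scales all take a `conformation` (or a list of them).
#'
#' When `fixed_bonds = TRUE` the constructor checks that every consecutive
#' pair of points is at distance `b` to a relative tolerance of 1e-9, which
#' is the contract the Monte Carlo movesets and the fixed-bond generators
#' guarantee.
#'
#' @param coords numeric matrix with n rows and 3 columns (x, y, z in
#'   angstrom), n >= 2.
#' @param b nominal bond length in angstrom.
#' @param labels optional character vector of length n with per-monomer
#'   classes from `"alpha"`, `"beta"`, `"loop"`, `"none"`.
#' @param fixed_bonds logical; if `TRUE` (default) consecutive distances are
#'   validated against `b`.
#' @return an object of class `conformation`: a list with elements `coords`,
#'   `b`, `labels`, `fixed_bonds`.
#' @examples
#' z <- conformation(cbind(0:4 * 3.81, 0, 0), b = 3.81)
#' n_monomers(z)
#' @export
conformation <- function(coords, b, labels = NULL, fixed_bonds = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("`coords` must have 3 columns (x, y, z)")
  n <- nrow(coords)
  if (n < 2L) stop("a conformation needs at least 2 points")
  if (!is.numeric(b) || length(b) != 1L || b <= 0)
    stop("`b` must be a single positive bond length")
  if (anyNA(coords)) stop("`coords` contains missing values")
  if (fixed_bonds) {
    d <- bond_lengths_matrix(coords)
    if (any(abs(d - b) > 1e-9 * b))
      stop("consecutive points deviate from bond length `b` ",
           "by more than 1e-9 relative (max deviation ",
           format(max(abs(d - b))), " A)")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n)
      stop("`labels` must have one entry per monomer")
    bad <- setdiff(unique(labels), c("alpha", "beta", "loop", "none"))
    if (length(bad))
      stop("unknown labels: ", paste(bad, collapse = ", "))
  }
  structure(list(coords = coords, b = b, labels = labels,
                 fixed_bonds = isTRUE(fixed_bonds)),
            class = "conformation")
}

bond_lengths_matrix <- function(coords) {
  d <- diff(coords)
  sqrt(rowSums(d * d))
}

#' @rdname conformation
#' @param x a `conformation`.
#' @export
n_monomers <- function(x) {
  stopifnot(inherits(x, "conformation"))
  nrow(x$coords)
}

#' @rdname conformation
#' @export
bond_lengths <- function(x) {
  stopifnot(inherits(x, "conformation"))
  bond_lengths_matrix(x$coords)
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", nrow(x$coords), " monomers, b = ",
      format(x$b), " A", sep = "")
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat(", labels: ", paste(names(tb), tb, sep = ":", collapse = " "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Straight (fully extended) chain
#'
#' Convenience constructor for an n-bead chain along the x axis, the
#' zero-energy reference state of the tangent-sphere model and the standard
#' initial state for the samplers.
#'
#' @param n number of beads.
#' @param b bond length in angstrom.
#' @param labels optional labels, recycled to length n.
#' @return a `conformation`.
#' @export
straight_chain <- function(n, b = 3.81, labels = NULL) {
  if (!is.null(labels)) labels <- rep_len(labels, n)
  conformation(cbind((seq_len(n) - 1) * b, 0, 0), b = b, labels = labels)
}

#' Read and write XYZ-style chain files
#'
#' The interchange format is whitespace-delimited text with one monomer per
#' row: `index x y z [label]`.  Coordinates are in angstrom.  A comment line
#' starting with `#` may carry `b=<bond length>`; otherwise `b` must be
#' given to the reader.
#'
#' @param conf a `conformation`.
#' @param path file path.
#' @rdname xyz_io
#' @export
write_chain_xyz <- function(conf, path) {
  stopifnot(inherits(conf, "conformation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chainscales xyz b=%.10g", conf$b), con)
  n <- nrow(conf$coords)
  lab <- if (is.null(conf$labels)) rep("", n) else paste0(" ", conf$labels)
  writeLines(sprintf("%d %.10g %.10g %.10g%s", seq_len(n),
                     conf$coords[, 1], conf$coords[, 2], conf$coords[, 3],
                     lab), con)
  invisible(path)
}

#' @param b bond length override; defaults to the value recorded in the
#'   file header.
#' @param fixed_bonds passed to [conformation()].
#' @rdname xyz_io
#' @export
read_chain_xyz <- function(path, b = NULL, fixed_bonds = TRUE) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  lines <- grep("^#", lines, value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  if (is.null(b)) {
    m <- regmatches(hdr, regexpr("b=[0-9.eE+-]+", hdr))
    m <- unlist(m)
    if (!length(m)) stop("no bond length in file header; supply `b`")
    b <- as.numeric(sub("b=", "", m[[1]]))
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf < 4L)) stop("malformed xyz line (need index x y z [label])")
  coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  labels <- if (all(nf >= 5L)) vapply(parts, `[[`, character(1), 5L) else NULL
  conformation(coords, b = b, labels = labels, fixed_bonds = fixed_bonds)
}

#' Write a CA-only PDB file for a conformation
#'
#' Emits one `ATOM` record per monomer (atom name CA, residue GLY, chain A)
#' in fixed-width PDB format, so the chain can be inspected with standard
#' structure viewers and read back with [read_calpha_trace()].  PDB
#' coordinates carry 3 decimals, so round-trips are exact to 1e-3 angstrom.
#'
#' @param conf a `conformation`.
#' @param path output path.
#' @param chain one-letter chain identifier.
#' @export
write_ca_pdb <- function(conf, path, chain = "A") {
  stopifnot(inherits(conf, "conformation"))
  n <- nrow(conf$coords)
  recs <- sprintf(
    "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), chain, seq_len(n),
    conf$coords[, 1], conf$coords[, 2], conf$coords[, 3])
  writeLines(c(recs, "TER", "END"), path)
  invisible(path)
}

#' Convert an MC snapshot array to a list of conformations
#'
#' The samplers return snapshots as a 3 x n x k array; this wraps each slice
#' as a `conformation` sharing the model's bond length.
#'
#' @param snaps 3 x n x k numeric array.
#' @param b bond length in angstrom.
#' @return list of `conformation` objects.
#' @export
snapshots_as_conformations <- function(snaps, b) {
  stopifnot(length(dim(snaps)) == 3L, dim(snaps)[1] == 3L)
  k <- dim(snaps)[3]
  lapply(seq_len(k), function(i)
    conformation(t(snaps[, , i]), b = b))
}
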