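# Geometry data model: molecules, XYZ I/O, centre of mass, inertial tensor
# and a 3x3 Jacobi eigen-solver.
#
# A molecule is a list with components
#   element  : character vector of element symbols (file order)
#   mass     : numeric vector, amu
#   xyz      : N x 3 matrix of cartesian positions, Angstrom
#   comment  : free-text comment line
# of class "molecule".  All pipeline functions centre coordinates on the
# centre of mass before use.

#' Construct a molecule
#'
#' @param element character vector of element symbols.
#' @param xyz N x 3 numeric matrix of cartesian coordinates (Angstrom).
#' @param mass optional numeric vector of per-atom masses (amu); defaults to
#'   standard atomic weights.
#' @param comment free-text comment.
#' @return an object of class \code{"molecule"}.
#' @export
molecule <- function(element, xyz, mass = NULL, comment = "") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (length(element) < 1L) stop("a molecule needs at least one atom")
  if (nrow(xyz) != length(element)) stop("element/coordinate length mismatch")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(mass)) mass <- atomic_mass(element)
  mass <- rep_len(as.numeric(mass), length(element))
  if (any(!is.finite(mass) | mass <= 0)) stop("masses must be positive and finite")
  structure(list(element = as.character(element), mass = mass, xyz = xyz,
                 comment = as.character(comment)[1]),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms (%s)\n", nrow(x$xyz),
              paste(names(sort(-table(x$element))), collapse = " ")))
  if (nzchar(x$comment)) cat(" comment:", x$comment, "\n")
  invisible(x)
}

#' Read an XYZ-format geometry
#'
#' Standard XYZ dialect: line 1 is the atom count, line 2 a free comment,
#' then one record per atom: \code{symbol x y z [mass]}, whitespace-separated,
#' coordinates in Angstrom.  The optional 5th column overrides the standard
#' atomic weight of that atom (e.g. to emulate isotope-broken symmetry).
#'
#' @param text either a path to an XYZ file or a character scalar holding the
#'   file contents (detected by the presence of a newline).
#' @return a \code{\link{molecule}}.
#' @export
read_xyz <- function(text) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    readLines(text) else strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  if (length(lines) < 1L) stop("empty XYZ input")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ line 1: atom count expected, got '", lines[1], "'")
  if (n < 1L) stop("XYZ line 1: atom count must be >= 1")
  comment <- if (length(lines) >= 2L) lines[2] else ""
  records <- lines[-(1:2)]
  records <- records[nzchar(trimws(records))]
  if (length(records) != n)
    stop(sprintf("XYZ count mismatch: header says %d atoms, found %d records",
                 n, length(records)))
  element <- character(n); mass <- rep(NA_real_, n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(records[i]), "[[:space:]]+")[[1]]
    if (length(tok) < 4L)
      stop("XYZ record line ", i + 2L, ": expected 'symbol x y z [mass]'")
    element[i] <- tok[1]
    v <- suppressWarnings(as.numeric(tok[2:min(5, length(tok))]))
    if (anyNA(v[1:3]))
      stop("XYZ record line ", i + 2L, ": non-numeric coordinate")
    xyz[i, ] <- v[1:3]
    if (length(v) >= 4L && !is.na(v[4])) mass[i] <- v[4]
  }
  default <- atomic_mass(element)
  mass <- ifelse(is.na(mass), default, mass)
  molecule(element, xyz, mass, comment)
}

#' Write a molecule in XYZ format
#'
#' @param mol a \code{\link{molecule}}.
#' @param path optional output path; when \code{NULL} the XYZ text is
#'   returned as a character scalar.
#' @param digits coordinate precision.
#' @return the XYZ text, invisibly when written to a file.
#' @export
write_xyz <- function(mol, path = NULL, digits = 10) {
  fmt <- sprintf("%%-3s %% .%df %% .%df %% .%df", digits, digits, digits)
  body <- sprintf(fmt, mol$element, mol$xyz[, 1], mol$xyz[, 2], mol$xyz[, 3])
  txt <- paste(c(nrow(mol$xyz), mol$comment, body), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Centre of mass
#'
#' @param mol a \code{\link{molecule}}.
#' @return mass-weighted mean position, a length-3 vector (Angstrom).
#' @export
center_of_mass <- function(mol) {
  drop(crossprod(mol$xyz, mol$mass)) / sum(mol$mass)
}

#' Centre a molecule on its centre of mass
#'
#' @param mol a \code{\link{molecule}}.
#' @return the molecule with positions made centre-of-mass relative.
#' @export
center_molecule <- function(mol) {
  com <- center_of_mass(mol)
  mol$xyz <- sweep(mol$xyz, 2, com)
  mol
}

#' Inertial tensor
#'
#' Mass-weighted second-moment tensor
#' \eqn{\sum_i m_i ((a_i \cdot a_i) E - a_i \otimes a_i)} of a set of point
#' masses with positions relative to the centre of mass.
#'
#' @param positions N x 3 matrix (Angstrom), centre-of-mass relative.
#' @param masses numeric vector (amu).
#' @return symmetric 3 x 3 matrix (amu Angstrom^2).
#' @export
inertial_tensor <- function(positions, masses) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  if (nrow(positions) != length(masses))
    stop("positions/masses length mismatch")
  r2 <- rowSums(positions^2)
  diag(sum(masses * r2), 3) - crossprod(positions * masses, positions)
}

#' Jacobi eigen-decomposition of a symmetric 3 x 3 matrix
#'
#' Classical cyclic Jacobi rotations; converges to machine precision in a
#' handful of sweeps for 3 x 3 input.
#'
#' @param m symmetric 3 x 3 matrix.
#' @return list with \code{values} (ascending) and \code{vectors}
#'   (columns; right-handed orthonormal triad).
#' @export
jacobi_eigen3 <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L))) stop("expected a 3x3 matrix")
  scale <- max(abs(m), 1e-300)
  if (max(abs(m - t(m))) > 1e-10 * scale) stop("matrix is not symmetric")
  a <- (m + t(m)) / 2
  v <- diag(3)
  for (sweep in 1:50) {
    off <- sqrt(a[1, 2]^2 + a[1, 3]^2 + a[2, 3]^2)
    if (off <= 1e-15 * scale) break
    for (idx in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
      p <- idx[1]; q <- idx[2]
      if (abs(a[p, q]) <= 1e-18 * scale) next
      theta <- (a[q, q] - a[p, p]) / (2 * a[p, q])
      t_ <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
      if (theta == 0) t_ <- 1
      c_ <- 1 / sqrt(t_^2 + 1); s_ <- t_ * c_
      g <- diag(3); g[p, p] <- c_; g[q, q] <- c_; g[p, q] <- s_; g[q, p] <- -s_
      a <- crossprod(g, a %*% g)
      a[p, q] <- 0; a[q, p] <- 0
      v <- v %*% g
    }
  }
  ord <- order(diag(a))
  values <- diag(a)[ord]
  vectors <- v[, ord, drop = FALSE]
  # enforce a right-handed triad and a canonical sign per column
  for (k in 1:3) {
    j <- which(abs(vectors[, k]) > 1e-12)[1]
    if (length(j) && !is.na(j) && vectors[j, k] < 0) vectors[, k] <- -vectors[, k]
  }
  if (det(vectors) < 0) vectors[, 3] <- -vectors[, 3]
  list(values = values, vectors = vectors)
}

#' Principal inertial frame and degeneracy classification
#'
#' Diagonalises the inertial tensor and classifies the moment pattern as
#' \code{"linear"}, \code{"spherical"} (triply degenerate),
#' \code{"symmetric-top"} (doubly degenerate) or \code{"asymmetric"}.
#'
#' @param positions N x 3 matrix, centre-of-mass relative (Angstrom).
#' @param masses numeric vector (amu).
#' @param tol_deg relative tolerance for treating two moments as equal.
#' @param tol_lin relative tolerance below which the smallest moment marks a
#'   linear arrangement.
#' @return list with \code{moments} (ascending, amu Angstrom^2), \code{axes}
#'   (columns, right-handed), \code{class}, and for symmetric tops
#'   \code{unique_axis} (index of the non-degenerate axis).
#' @export
inertial_frame <- function(positions, masses, tol_deg = 1e-4, tol_lin = 1e-6) {
  eig <- jacobi_eigen3(inertial_tensor(positions, masses))
  mom <- eig$values
  big <- max(mom, 0)
  cls <- "asymmetric"; unique_axis <- NA_integer_
  if (big <= 0) {
    cls <- "spherical"            # single point at the origin
  } else if (mom[1] <= tol_lin * big) {
    cls <- "linear"; unique_axis <- 1L
  } else {
    eq12 <- abs(mom[1] - mom[2]) <= tol_deg * big
    eq23 <- abs(mom[2] - mom[3]) <= tol_deg * big
    if (eq12 && eq23) cls <- "spherical"
    else if (eq12) { cls <- "symmetric-top"; unique_axis <- 3L }
    else if (eq23) { cls <- "symmetric-top"; unique_axis <- 1L }
  }
  list(moments = mom, axes = eig$vectors, class = cls, unique_axis = unique_axis)
}
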