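# Equivalence sets: partition atoms into orbits of symmetry-equivalent
# nuclei by clustering symmetry-invariant per-atom properties, with
# recursive refinement inside each subset.

#' Reduced-mass weighted euclidean distance matrix
#'
#' \eqn{D_{ij} = \mu_{ij} |a_i - a_j|} with the reduced mass
#' \eqn{\mu_{ij} = m_i m_j / (m_i + m_j)}.
#'
#' @param mol a centred \code{\link{molecule}}.
#' @return symmetric N x N matrix (amu Angstrom) with zero diagonal.
#' @export
weighted_distance_matrix <- function(mol) {
  d <- as.matrix(stats::dist(mol$xyz))
  m <- mol$mass
  mu <- outer(m, m) / outer(m, m, "+")
  dm <- mu * d
  diag(dm) <- 0
  dm
}

#' Symmetry-invariant property vector of one atom
#'
#' Four per-atom scalars that are invariant under any isometry permuting
#' equal-mass atoms: mean and euclidean length of the atom's row of the
#' weighted distance matrix, and the norms of the reduced-mass weighted
#' projections onto a unit sphere (\eqn{s_i}) and onto the plane
#' perpendicular to the atom's own position (\eqn{p_i}).
#'
#' @param mol a centred \code{\link{molecule}} with at least 2 atoms.
#' @param i atom index.
#' @param dm optional precomputed \code{\link{weighted_distance_matrix}}.
#' @return list with \code{row_mean}, \code{row_norm}, \code{sphere_norm},
#'   \code{plane_norm}, and \code{origin_flag} (TRUE when the atom sits at
#'   the origin and the plane projection term was dropped).
#' @export
invariant_vector <- function(mol, i, dm = NULL) {
  n <- nrow(mol$xyz)
  if (n < 2L) stop("invariants need at least two atoms")
  if (is.null(dm)) dm <- weighted_distance_matrix(mol)
  row <- dm[i, -i]
  m <- mol$mass
  mu <- m[i] * m[-i] / (m[i] + m[-i])
  dvec <- sweep(mol$xyz[-i, , drop = FALSE], 2, mol$xyz[i, ], "-")
  dlen <- sqrt(rowSums(dvec^2))
  svec <- colSums(mu * dvec / pmax(dlen, 1e-300))
  ai <- mol$xyz[i, ]
  ai2 <- sum(ai^2)
  origin_flag <- ai2 < 1e-20
  aj <- mol$xyz[-i, , drop = FALSE]
  pvec <- if (origin_flag) colSums(mu * aj) else
    colSums(mu * (aj - outer(drop(aj %*% ai) / ai2, ai)))
  list(row_mean = mean(row), row_norm = sqrt(sum(row^2)),
       sphere_norm = sqrt(sum(svec^2)), plane_norm = sqrt(sum(pvec^2)),
       origin_flag = origin_flag)
}

#' Per-atom inertial-eigenvalue invariants
#'
#' An alternative symmetry-invariant property: the three eigenvalues of the
#' inertial tensor of the whole molecule evaluated with its origin at each
#' atom in turn.  Offered as an optional clustering signal alongside the
#' default projection-based invariants.
#'
#' @param mol a centred \code{\link{molecule}}.
#' @return N x 3 matrix of ascending eigenvalues (amu Angstrom^2).
#' @export
inertial_invariants <- function(mol) {
  n <- nrow(mol$xyz)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    d <- sweep(mol$xyz, 2, mol$xyz[i, ])
    out[i, ] <- jacobi_eigen3(inertial_tensor(d, mol$mass))$values
  }
  colnames(out) <- c("I1", "I2", "I3")
  out
}

.invariant_matrix <- function(mol, subset = NULL) {
  idx <- if (is.null(subset)) seq_len(nrow(mol$xyz)) else subset
  sub <- mol
  sub$xyz <- mol$xyz[idx, , drop = FALSE]
  sub$mass <- mol$mass[idx]
  sub$element <- mol$element[idx]
  if (length(idx) == 1L)
    return(matrix(0, 1, 4, dimnames = list(NULL,
      c("row_mean", "row_norm", "sphere_norm", "plane_norm"))))
  dm <- weighted_distance_matrix(sub)
  t(vapply(seq_along(idx), function(k) {
    v <- invariant_vector(sub, k, dm)
    c(row_mean = v$row_mean, row_norm = v$row_norm,
      sphere_norm = v$sphere_norm, plane_norm = v$plane_norm)
  }, numeric(4)))
}

#' Cluster atoms by their invariant vectors
#'
#' Single-linkage clustering within a tolerance: two members are linked when
#' every invariant component agrees within \code{rel_tol} relative to that
#' component's scale over the set; clusters are connected components,
#' reported in canonical order (lowest member first).
#'
#' @param vectors numeric matrix, one row per member, columns = invariant
#'   components.
#' @param rel_tol relative agreement tolerance.
#' @return list of integer vectors partitioning \code{seq_len(nrow(vectors))}.
#' @export
cluster_invariants <- function(vectors, rel_tol = 0.1) {
  v <- as.matrix(vectors)
  n <- nrow(v)
  if (n == 1L) return(list(1L))
  # tolerance relative to the overall invariant magnitude: components of a
  # symmetric orbit cancel almost completely, so their own spread is noise,
  # not signal
  glob <- max(abs(v), 1e-12)
  scale <- rep(glob, ncol(v))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (all(abs(v[i, ] - v[j, ]) <= rel_tol * scale)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  out <- split(seq_len(n), roots)
  out <- out[order(vapply(out, min, 0L))]
  unname(out)
}

#' Refine an equivalence partition to a fixed point
#'
#' Recomputes the invariant vectors inside each subset treated as its own
#' molecule (same centre) and re-clusters, repeating until stable.  The
#' result always refines the input partition (sets are only ever split).
#'
#' @param mol a centred \code{\link{molecule}}.
#' @param partition list of integer index vectors.
#' @param rel_tol clustering tolerance.
#' @return refined partition (canonical order).
#' @export
refine_partition <- function(mol, partition, rel_tol = 0.1) {
  repeat {
    out <- list()
    changed <- FALSE
    for (set in partition) {
      if (length(set) <= 1L) { out[[length(out) + 1L]] <- set; next }
      v <- .invariant_matrix(mol, set)
      cl <- cluster_invariants(v, rel_tol)
      if (length(cl) > 1L) changed <- TRUE
      for (c_ in cl) out[[length(out) + 1L]] <- set[c_]
    }
    partition <- out[order(vapply(out, min, 0L))]
    if (!changed) return(partition)
  }
}

#' Partition a molecule into equivalence sets
#'
#' Atoms are first grouped exactly by (element, mass); within each group the
#' four invariant properties are clustered, and the partition is refined
#' recursively.  For orbit geometries the result equals the orbits of the
#' point group.
#'
#' @param mol a \code{\link{molecule}} (centred internally).
#' @param rel_tol clustering tolerance.
#' @param invariant \code{"projection"} (default: distance-row statistics
#'   plus sphere/plane projections) or \code{"inertia"} (per-atom inertial
#'   eigenvalues, see \code{\link{inertial_invariants}}).
#' @return list of integer index vectors (disjoint, covering all atoms,
#'   canonical order).
#' @export
equivalence_sets <- function(mol, rel_tol = 0.1,
                             invariant = c("projection", "inertia")) {
  invariant <- match.arg(invariant)
  mol <- center_molecule(mol)
  key <- paste(mol$element, signif(mol$mass, 10))
  groups <- split(seq_along(key), key)
  inv <- if (invariant == "inertia") inertial_invariants(mol) else
    .invariant_matrix(mol)
  partition <- list()
  for (g in groups) {
    cl <- cluster_invariants(inv[g, , drop = FALSE], rel_tol)
    for (c_ in cl) partition[[length(partition) + 1L]] <- g[c_]
  }
  partition <- partition[order(vapply(partition, min, 0L))]
  refine_partition(mol, partition, rel_tol)
}
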