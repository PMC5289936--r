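# Symmetrisation of near-symmetric geometries (projection onto the totally
# symmetric subspace of the atom (x) cartesian displacement space) and of
# molecular-orbital coefficient sets (projection onto the dominant irrep's
# SALC span, with partner averaging for degenerate irreps).

#' Project a geometry onto the totally symmetric space of a group
#'
#' Stacks the atomic positions as one vector in the (atom x cartesian)
#' space and applies the totally symmetric projector built from the
#' permutation action and the 3 x 3 operation matrices.  The discarded
#' component's mass-weighted norm is the error indicator; the result is
#' exactly invariant under every group operation.
#'
#' @param mol a \code{\link{molecule}}.
#' @param group a \code{point_group} whose operations map each equivalence
#'   set onto itself within \code{tol_geom}.
#' @param tol_geom matching tolerance (Angstrom).
#' @return list with \code{molecule} (symmetrised, centred), \code{error}
#'   (mass-weighted residual norm, sqrt(amu) Angstrom), \code{rms}
#'   (unweighted per-atom RMS displacement, Angstrom).
#' @export
symmetrize_molecule <- function(mol, group, tol_geom = 0.05) {
  mol <- center_molecule(mol)
  X <- mol$xyz
  n <- nrow(X)
  sets <- if (!is.null(group$sets)) group$sets else equivalence_sets(mol)
  acc <- matrix(0, n, 3)
  for (o in group$ops) {
    im <- X %*% t(o$matrix)
    perm <- integer(n)
    for (s in sets) {
      p <- .match_points(im[s, , drop = FALSE], X[s, , drop = FALSE],
                         tol_geom)
      if (anyNA(p))
        stop("operation ", .op_name(o), " does not permute the molecule ",
             "within tol_geom")
      perm[s] <- s[p]
    }
    acc[perm, ] <- acc[perm, ] + im
  }
  Y <- acc / group$order
  d2 <- rowSums((X - Y)^2)
  err <- sqrt(sum(mol$mass * d2))
  rms <- sqrt(mean(d2))
  if (n > 1L && min(stats::dist(Y)) < 1e-3)
    stop("symmetrisation collapses atoms; the group is inconsistent with ",
         "the geometry")
  out <- mol
  out$xyz <- Y
  list(molecule = center_molecule(out), error = err, rms = rms)
}

# component-major SALC stacks for one irrep: list over components k of
# matrices T_k (total multiplicity x basis), plus bookkeeping
.irrep_stacks <- function(salcs, irrep_name) {
  sp <- Filter(function(s) s$irrep == irrep_name, salcs$spaces)
  if (length(sp) == 0L) return(NULL)
  d <- sp[[1]]$dim
  comps <- vector("list", d)
  for (k in seq_len(d)) {
    rows <- Filter(function(s) s$component == k, sp)
    comps[[k]] <- do.call(rbind, lapply(rows, `[[`, "coef"))
  }
  comps
}

#' Per-orbital irrep composition against a SALC basis
#'
#' @param orbitals coefficient matrix (orbitals x basis functions) over the
#'   same basis ordering as the SALCs; rows are re-normalised (with a
#'   warning) when they deviate from unit norm by more than 1e-8.
#' @param salcs a \code{salc_set}.
#' @return object of class \code{"symmetry_report"}: data.frame with one
#'   row per orbital (\code{orbital}, \code{irrep}, \code{fraction}) and
#'   the full fraction matrix in \code{attr(, "fractions")}.
#' @export
analyze_orbital_symmetry <- function(orbitals, salcs) {
  C <- as.matrix(orbitals)
  if (ncol(C) != nrow(salcs$basis))
    stop("orbital basis size does not match the SALC basis")
  nrm <- sqrt(rowSums(C^2))
  if (any(abs(nrm - 1) > 1e-8)) {
    warning("orbital rows re-normalised")
    C <- C / nrm
  }
  irr <- unique(vapply(salcs$spaces, `[[`, "", "irrep"))
  frac <- matrix(0, nrow(C), length(irr), dimnames = list(NULL, irr))
  for (j in seq_along(irr)) {
    Tk <- do.call(rbind, .irrep_stacks(salcs, irr[j]))
    frac[, j] <- rowSums((C %*% t(Tk))^2)
  }
  if (any(abs(rowSums(frac) - 1) > 1e-8))
    stop("irrep fractions do not sum to 1; bases are inconsistent")
  best <- max.col(frac, ties.method = "first")
  rep <- data.frame(orbital = seq_len(nrow(C)), irrep = irr[best],
                    fraction = frac[cbind(seq_len(nrow(C)), best)])
  attr(rep, "fractions") <- frac
  class(rep) <- c("symmetry_report", "data.frame")
  rep
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat("orbital symmetry report:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Symmetrise a set of molecular orbitals against a SALC basis
#'
#' Each orbital is projected onto the span of its dominant irrep and
#' re-normalised.  For degenerate irreps the orbitals are grouped into
#' partner sets by their multiplicity-space component vectors, an average
#' component is computed per set, and the orbitals are rotated to align
#' with the symmetry-adapted basis functions, so the output partner sets
#' transform exactly into each other under the group.  Orbitals of one
#' irrep are Loewdin-orthonormalised so the output is orthonormal within
#' each irrep.
#'
#' @inheritParams analyze_orbital_symmetry
#' @param min_component smallest acceptable dominant-irrep fraction;
#'   below it the input is rejected as too symmetry-broken.
#' @return list with \code{orbitals} (symmetrised coefficients, same order)
#'   and \code{report} (the input \code{\link{analyze_orbital_symmetry}}
#'   report augmented with partner \code{component} assignments).
#' @export
symmetrize_wavefunction <- function(orbitals, salcs, min_component = 0.5) {
  C <- as.matrix(orbitals)
  rep_in <- analyze_orbital_symmetry(C, salcs)
  if (any(rep_in$fraction <= min_component))
    stop("orbital(s) ", paste(which(rep_in$fraction <= min_component),
                              collapse = ", "),
         " have no irrep component above min_component = ", min_component,
         "; input is too symmetry broken")
  nrm <- sqrt(rowSums(C^2)); C <- C / nrm
  out <- C
  component <- integer(nrow(C))
  for (ir in unique(rep_in$irrep)) {
    idx <- which(rep_in$irrep == ir)
    stacks <- .irrep_stacks(salcs, ir)
    d <- length(stacks)
    M <- nrow(stacks[[1]])
    if (d == 1L) {
      B <- C[idx, , drop = FALSE] %*% t(stacks[[1]])   # orbitals x M
      B <- .loewdin_rows(B)
      out[idx, ] <- B %*% stacks[[1]]
      component[idx] <- 1L
      next
    }
    A <- lapply(seq_len(d), function(k)
      C[idx, , drop = FALSE] %*% t(stacks[[k]]))       # per k: orbitals x M
    W <- vapply(A, function(a) rowSums(a^2), numeric(length(idx)))
    W <- matrix(W, nrow = length(idx))
    dom <- max.col(W, ties.method = "first")
    mdir <- t(vapply(seq_along(idx), function(i) {
      v <- A[[dom[i]]][i, ]
      v / sqrt(sum(v^2))
    }, numeric(M)))
    # partner grouping by multiplicity-space direction
    gid <- integer(length(idx))
    for (i in seq_along(idx)) {
      if (gid[i] != 0L) next
      g <- max(gid) + 1L
      gid[i] <- g
      for (j in seq_along(idx)) {
        if (gid[j] != 0L || dom[j] == dom[i]) next
        if (abs(sum(mdir[i, ] * mdir[j, ])) > 0.7 &&
            !any(dom[gid == g] == dom[j]))
          gid[j] <- g
      }
    }
    avg <- NULL
    for (g in seq_len(max(gid))) {
      mem <- which(gid == g)
      ref <- mdir[mem[1], ]
      vs <- vapply(mem, function(i)
        sign(sum(mdir[i, ] * ref) + 1e-300) * mdir[i, ], numeric(M))
      a <- rowMeans(matrix(vs, nrow = M))
      avg <- rbind(avg, a / sqrt(sum(a^2)))
    }
    avg <- .loewdin_rows(avg)
    for (i in seq_along(idx)) {
      a <- avg[gid[i], ]
      out[idx[i], ] <- drop(a %*% stacks[[dom[i]]])
      component[idx[i]] <- dom[i]
    }
  }
  rep_in$component <- component
  rep_out <- analyze_orbital_symmetry(out, salcs)
  rep_in$final_fraction <- rep_out$fraction
  list(orbitals = out, report = rep_in)
}

# symmetric (Loewdin) orthonormalisation of the rows of a matrix
.loewdin_rows <- function(B) {
  S <- tcrossprod(B)
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values < 1e-10))
    stop("orbitals within one irrep are linearly dependent after projection")
  Sm <- e$vectors %*% diag(1 / sqrt(e$values), nrow(S)) %*% t(e$vectors)
  Sm %*% B
}
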