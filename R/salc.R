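# Symmetry-adapted linear combinations.
#
# For every (equivalence set, shell) block a direct-product representation
# D^{SY}(R) = D^S(R) (x) D^Y(R) is formed from the permutation action on the
# set and the real-spherical-harmonic rotation matrices.  Trace projection
# operators built from the character table project out each irrep's
# subspace; pivoted Cholesky extraction gives orthonormal spanning rows; and
# subduction to a splitting subgroup (recursively, for the icosahedral
# 5-dimensional irreps) separates the partner components, which are then
# rotated into a similarly oriented basis by a fixed group operation outside
# the splitting subgroup, so partner orientation is identical across
# equivalence sets and shells.

#' Direct-product representation of one block
#'
#' @param perm_rep list of permutations (images) of the set, one per
#'   operation.
#' @param shell_matrices list of (2l+1) x (2l+1) matrices, one per
#'   operation, same order.
#' @return list of |S|(2l+1) square matrices \eqn{D^{SY}(R) = D^S(R)
#'   \otimes D^Y(R)}, basis ordered atom-major (atom, then m).
#' @export
direct_product_rep <- function(perm_rep, shell_matrices) {
  if (length(perm_rep) != length(shell_matrices))
    stop("operation lists differ in length")
  ns <- length(perm_rep[[1]])
  lapply(seq_along(perm_rep), function(i) {
    p <- perm_rep[[i]]
    P <- matrix(0, ns, ns)
    P[cbind(p, seq_len(ns))] <- 1
    P %x% shell_matrices[[i]]
  })
}

#' Trace projection operator for one irrep
#'
#' \eqn{P^\Gamma = (\dim\Gamma / |G|) \sum_R \chi^\Gamma(R) D(R)};
#' idempotent with trace \eqn{m_\Gamma \dim\Gamma}.
#'
#' @param table a \code{character_table}.
#' @param irrep irrep index (or name) in the table.
#' @param rep list of representation matrices, one per group operation in
#'   the table's operation order.
#' @param check verify idempotency.
#' @return the projector matrix.
#' @export
trace_projector <- function(table, irrep, rep, check = TRUE) {
  if (is.character(irrep))
    irrep <- match(irrep, vapply(table$irreps, `[[`, "", "name"))
  chi <- .chi_of_ops(table, irrep)
  # merged complex-pair rows are sums of two projectors, so the prefactor
  # carries dim/s, not dim
  dimG <- table$irreps[[irrep]]$dim / table$irreps[[irrep]]$s
  P <- Reduce(`+`, Map(`*`, chi, rep)) * (dimG / table$order)
  if (check && max(abs(P %*% P - P)) > 1e-9)
    stop("trace projector is not idempotent; representation and table disagree")
  (P + t(P)) / 2
}

# deterministic orthonormalisation of the rows of a matrix (largest-norm
# pivot first, ties by index; canonical sign: largest-magnitude entry > 0)
.orthonormal_rows <- function(m, rank = NULL, tol = 1e-8) {
  out <- NULL
  rem <- m
  repeat {
    nrm <- sqrt(rowSums(rem^2))
    j <- which.max(round(nrm, 10))
    if (length(j) == 0L || nrm[j] < tol) break
    v <- rem[j, ] / nrm[j]
    k <- which.max(abs(round(v, 10)))
    if (v[k] < 0) v <- -v
    out <- rbind(out, v)
    rem <- rem - outer(drop(rem %*% v), v)
    if (!is.null(rank) && nrow(out) >= rank) break
  }
  if (!is.null(rank) && (is.null(out) || nrow(out) != rank))
    stop("rank deficiency during orthonormalisation")
  out
}

#' Orthonormal rows spanning the image of a projector
#'
#' Pivoted Cholesky factorisation of the idempotent symmetric projector
#' (largest diagonal first, ties by lowest index) followed by a
#' Gram-Schmidt polish; deterministic given the fixed pivot rule.
#'
#' @param P projector matrix (symmetric, idempotent).
#' @param tol diagonal threshold.
#' @return matrix with rank(P) orthonormal rows spanning the image (NULL
#'   when the projector vanishes).
#' @export
extract_subspace <- function(P, tol = 1e-8) {
  r <- as.integer(round(sum(diag(P))))
  if (abs(sum(diag(P)) - r) > 1e-6)
    stop("projector trace is not close to an integer")
  if (r == 0L) return(NULL)
  rem <- P
  cols <- matrix(0, nrow(P), r)
  for (k in seq_len(r)) {
    d <- diag(rem)
    p <- which.max(round(d, 10))
    if (d[p] < tol) stop("projector rank below its trace")
    v <- rem[, p] / sqrt(d[p])
    cols[, k] <- v
    rem <- rem - tcrossprod(v)
  }
  B <- .orthonormal_rows(t(cols), rank = r)
  if (max(abs(B %*% P - B)) > 1e-8)
    stop("extracted vectors are not in the projector image")
  B
}

# ---- subduction ------------------------------------------------------------

#' Subduce an irrep of a group to a subgroup
#'
#' Multiplicities of each irrep of H in the restriction of one irrep of G,
#' by the reduction formula summed over H's operations (merged complex-pair
#' rows count once via their endomorphism factor).
#'
#' @param table_G character table of G.
#' @param irrep irrep index (or name) in \code{table_G}.
#' @param subgroup an H as returned by \code{\link{subgroup_point_group}}
#'   (carries \code{parent_indices} into G's operation list).
#' @param table_H character table of H.
#' @return named integer vector of multiplicities over H's irreps.
#' @export
subduce <- function(table_G, irrep, subgroup, table_H) {
  if (is.character(irrep))
    irrep <- match(irrep, vapply(table_G$irreps, `[[`, "", "name"))
  chiG <- .chi_of_ops(table_G, irrep)[subgroup$parent_indices]
  s <- vapply(table_H$irreps, `[[`, 0L, "s")
  m <- as.numeric(table_H$chi[, table_H$class_of_op, drop = FALSE] %*% chiG) /
    (subgroup$order * s)
  if (any(abs(m - round(m)) > 1e-8))
    stop("non-integer subduction multiplicity")
  m <- as.integer(round(m))
  names(m) <- vapply(table_H$irreps, `[[`, "", "name")
  m
}

# does a table contain merged complex-pair rows?
.has_complex_rows <- function(tab)
  any(vapply(tab$irreps, function(ir) isTRUE(ir$complex_pair), TRUE))

#' Choose a splitting subgroup chain for a degenerate irrep
#'
#' Deterministically selects the smallest subgroup H whose character table
#' has only real rows (irreps with complex characters are avoided) and in
#' which the irrep subduces multiplicity-free into at least two distinct
#' constituents; any still-degenerate constituent is split recursively
#' inside H.  For the 5-dimensional icosahedral irreps this produces the
#' two-step chain through D5 and C2.
#'
#' @param group a \code{point_group}.
#' @param table its character table.
#' @param irrep irrep index (or name).
#' @param subgroups optional pre-enumerated subgroup list of \code{group}.
#' @return a splitting tree: list with \code{subgroup} (a
#'   \code{point_group} whose \code{parent_indices} refer to the original
#'   group), \code{table}, and \code{constituents} — a list of
#'   \code{list(irrep, name, tree)} where \code{tree} is NULL for
#'   1-dimensional leaves.  Returns NULL for 1-dimensional input irreps.
#' @export
choose_splitting_subgroup <- function(group, table, irrep, subgroups = NULL) {
  if (is.character(irrep))
    irrep <- match(irrep, vapply(table$irreps, `[[`, "", "name"))
  dG <- table$irreps[[irrep]]$dim
  if (dG == 1L) return(NULL)
  if (is.null(subgroups)) subgroups <- enumerate_subgroups(group)
  for (sub in subgroups) {
    if (sub$order <= 1L || sub$order >= group$order) next
    H <- subgroup_point_group(group, sub$indices)
    tab_H <- generate_character_table(H)
    if (.has_complex_rows(tab_H)) next
    m <- tryCatch(subduce(table, irrep, H, tab_H), error = function(e) NULL)
    if (is.null(m) || any(m > 1L) || sum(m > 0L) < 2L) next
    cons <- list()
    ok <- TRUE
    for (gi in which(m == 1L)) {
      dH <- tab_H$irreps[[gi]]$dim
      child <- NULL
      if (dH > 1L) {
        grand <- enumerate_subgroups(H)
        child <- choose_splitting_subgroup(H, tab_H, gi, grand)
        if (is.null(child)) { ok <- FALSE; break }
      }
      cons[[length(cons) + 1L]] <- list(irrep = gi,
                                        name = tab_H$irreps[[gi]]$name,
                                        tree = child)
    }
    if (!ok) next
    return(list(subgroup = H, table = tab_H, constituents = cons))
  }
  stop("no splitting subgroup found for irrep ",
       table$irreps[[irrep]]$name, " of ", group$label)
}

# leaves of a splitting tree: each a list of stages, a stage being
# list(parent_indices of H's ops mapped into the ROOT group, chi values over
# those ops, dim, order); applied as a product of stage projectors.
.splitting_leaves <- function(tree, parent_map = NULL) {
  if (is.null(tree)) return(list(list()))   # single leaf, no projector stages
  idx <- tree$subgroup$parent_indices
  if (!is.null(parent_map)) idx <- parent_map[idx]
  out <- list()
  for (con in tree$constituents) {
    chi <- tree$table$chi[con$irrep, tree$table$class_of_op]
    stage <- list(ops = idx, chi = chi,
                  dim = tree$table$irreps[[con$irrep]]$dim /
                    tree$table$irreps[[con$irrep]]$s,
                  order = tree$subgroup$order, name = con$name)
    if (is.null(con$tree)) {
      out[[length(out) + 1L]] <- list(stage)
    } else {
      for (leaf in .splitting_leaves(con$tree, idx))
        out[[length(out) + 1L]] <- c(list(stage), leaf)
    }
  }
  out
}

# projector of one leaf in a concrete representation (list of matrices per
# root-group op)
.leaf_projector <- function(leaf, rep) {
  n <- nrow(rep[[1]])
  P <- diag(n)
  for (stage in leaf) {
    Ps <- Reduce(`+`, Map(`*`, stage$chi, rep[stage$ops])) *
      (stage$dim / stage$order)
    P <- Ps %*% P
  }
  (P + t(P)) / 2
}

# ---- basis bookkeeping -----------------------------------------------------

#' Basis-function table for a molecule and shell specification
#'
#' @param mol a \code{\link{molecule}}.
#' @param basis_spec either a named list mapping element symbols to integer
#'   vectors of shell angular momenta (e.g. \code{list(C = c(0, 1), H = 0)})
#'   or an unnamed list with one integer vector per atom.
#' @return data.frame with columns \code{atom}, \code{slot}, \code{l},
#'   \code{m}, one row per basis function, in the global basis order
#'   (atoms in molecule order, declared shells per atom, m = -l..l).
#' @export
basis_table <- function(mol, basis_spec) {
  n <- nrow(mol$xyz)
  shells <- if (!is.null(names(basis_spec))) {
    missing <- setdiff(unique(mol$element), names(basis_spec))
    if (length(missing) > 0L)
      stop("basis_spec lacks shells for element(s): ",
           paste(missing, collapse = ", "))
    lapply(mol$element, function(e) as.integer(basis_spec[[e]]))
  } else {
    if (length(basis_spec) != n)
      stop("per-atom basis_spec must have one entry per atom")
    lapply(basis_spec, as.integer)
  }
  rows <- list()
  for (a in seq_len(n)) for (s in seq_along(shells[[a]])) {
    l <- shells[[a]][s]
    rows[[length(rows) + 1L]] <- data.frame(atom = a, slot = s, l = l,
                                            m = seq(-l, l))
  }
  do.call(rbind, rows)
}

# ---- orchestration ---------------------------------------------------------

#' Build symmetry-adapted linear combinations
#'
#' Loops over (equivalence set, shell) blocks, forms the direct-product
#' representation, projects every irrep with non-zero multiplicity, extracts
#' orthonormal spanning rows, and determines similarly oriented partner
#' components through the splitting-subgroup chain.  The union of all SALC
#' rows is a complete orthonormal basis of the declared function space.
#'
#' @param mol a \code{\link{molecule}}.
#' @param basis_spec see \code{\link{basis_table}}.
#' @param group optional \code{point_group} (detected when NULL).  Linear
#'   molecules are handled through the finite surrogate group.
#' @param tol_geom geometric tolerance for the permutation action.
#' @return object of class \code{"salc_set"}: list with \code{group},
#'   \code{table}, \code{molecule}, \code{sets}, \code{basis} (the
#'   \code{\link{basis_table}}), and \code{spaces} — one record per
#'   (set, shell, irrep, partner component) with the orthonormal
#'   \code{coef} rows over the global basis.
#' @export
build_salcs <- function(mol, basis_spec, group = NULL, tol_geom = 0.05) {
  mol <- center_molecule(mol)
  if (is.null(group)) group <- detect_point_group(mol, tol_geom)
  if (identical(group$label, "Kh"))
    stop("single-atom spherical symmetry: SALC construction is refused; ",
         "every shell is already symmetry-adapted")
  basis <- basis_table(mol, basis_spec)
  if (inherits(group, "linear_point_group")) {
    lg <- linear_group_table(group$label, l_max = max(basis$l),
                             align = .frame_from_axis(group$axis))
    sets <- group$sets
    table <- lg$table
    group <- lg$group
    group$sets <- sets
  } else {
    table <- generate_character_table(group)
  }
  sets <- if (!is.null(group$sets)) group$sets else equivalence_sets(mol)
  nb <- nrow(basis)
  irr_names <- vapply(table$irreps, `[[`, "", "name")
  # shell layout must agree within a set
  spaces <- list()
  trees <- list()      # per irrep: splitting tree (computed once)
  gen_choice <- list() # per (irrep, leaf): fixed generator op index
  subs <- NULL
  for (si in seq_along(sets)) {
    set <- sets[[si]]
    sh <- unique(lapply(set, function(a) basis$l[basis$atom == a &
                                                   basis$m == -basis$l]))
    shell_list <- basis[basis$atom == set[1] & basis$m == -basis$l,
                        c("slot", "l")]
    for (a in set[-1]) {
      other <- basis[basis$atom == a & basis$m == -basis$l, c("slot", "l")]
      if (!identical(other$l, shell_list$l))
        stop("atoms of one equivalence set carry different shell lists")
    }
    perms <- permutation_representation(group, mol$xyz[set, , drop = FALSE],
                                        tol = tol_geom)
    for (k in seq_len(nrow(shell_list))) {
      slot <- shell_list$slot[k]; l <- shell_list$l[k]
      rows_global <- which(basis$atom %in% set & basis$slot == slot)
      shell_mats <- lapply(group$ops, function(o) operation_matrix(l, o))
      rep <- direct_product_rep(perms, shell_mats)
      span <- irrep_span_rep(table, rep)
      for (gi in which(span > 0L)) {
        P <- trace_projector(table, gi, rep)
        V <- extract_subspace(P)
        dG <- table$irreps[[gi]]$dim
        mG <- span[gi]
        if (dG == 1L) {
          spaces[[length(spaces) + 1L]] <- list(
            irrep = irr_names[gi], irrep_index = gi, dim = 1L,
            component = 1L, component_name = irr_names[gi],
            set = si, slot = slot, l = l, mult = mG,
            coef = .embed_rows(V, rows_global, nb))
          next
        }
        if (isTRUE(table$irreps[[gi]]$complex_pair)) {
          comps <- .split_pair_components(table$irreps[[gi]], V, rep,
                                          table$order, mG)
          for (ck in seq_along(comps))
            spaces[[length(spaces) + 1L]] <- list(
              irrep = irr_names[gi], irrep_index = gi, dim = dG,
              component = ck, component_name = paste0(irr_names[gi], ".", ck),
              set = si, slot = slot, l = l, mult = mG,
              coef = .embed_rows(comps[[ck]], rows_global, nb))
          next
        }
        key <- as.character(gi)
        if (is.null(trees[[key]])) {
          if (is.null(subs)) subs <- enumerate_subgroups(group)
          trees[[key]] <- choose_splitting_subgroup(group, table, gi, subs)
        }
        leaves <- .splitting_leaves(trees[[key]])
        if (length(leaves) != dG)
          stop("splitting tree does not yield dim(irrep) leaves")
        W1 <- .orthonormal_rows(V %*% .leaf_projector(leaves[[1]], rep),
                                rank = mG)
        comps <- vector("list", dG)
        comps[[1]] <- W1
        for (ck in seq_len(dG)[-1]) {
          Pk <- .leaf_projector(leaves[[ck]], rep)
          gkey <- paste(gi, ck)
          cand_ops <- gen_choice[[gkey]]
          if (is.null(cand_ops)) cand_ops <- seq_len(group$order)
          done <- FALSE
          for (oi in cand_ops) {
            Wk <- W1 %*% t(rep[[oi]]) %*% Pk
            lam <- sqrt(rowSums(Wk^2))
            if (min(lam) > 0.2 && diff(range(lam)) < 1e-6 * max(lam) + 1e-9) {
              comps[[ck]] <- Wk / lam[1]
              gen_choice[[gkey]] <- oi
              done <- TRUE
              break
            }
          }
          if (!done)
            stop("no generator connects partner components of irrep ",
                 irr_names[gi])
        }
        leafnames <- vapply(leaves, function(lf)
          paste(vapply(lf, `[[`, "", "name"), collapse = "."), "")
        for (ck in seq_len(dG))
          spaces[[length(spaces) + 1L]] <- list(
            irrep = irr_names[gi], irrep_index = gi, dim = dG,
            component = ck, component_name = leafnames[ck],
            set = si, slot = slot, l = l, mult = mG,
            coef = .embed_rows(comps[[ck]], rows_global, nb))
      }
    }
  }
  total <- sum(vapply(spaces, function(s) nrow(s$coef), 0L))
  if (total != nb)
    stop("SALC rows (", total, ") do not span the basis (", nb, ")")
  structure(list(group = group, table = table, molecule = mol, sets = sets,
                 basis = basis, spaces = spaces,
                 splitting = trees),
            class = "salc_set")
}

# Partner components of a merged complex-pair space.
#
# Surrogate linear-group pairs carry the two constituent 1-dim rows
# (pair_rows): components come from their projectors.  True complex pairs
# (cyclic families, T, Th) have no real 1-dim split; instead a group
# operation acting as a non-trivial rotation inside the pair plane defines
# a deterministic split: for each multiplicity copy pick a pivot vector u,
# set w = (R u - cos(a) u)/sin(a).  The generator then acts as the same
# 2x2 rotation on (u, w) in every block, so partner orientation is
# consistent across equivalence sets and shells.
.split_pair_components <- function(ir, V, rep, order, mG) {
  if (!is.null(ir$pair_rows)) {
    out <- lapply(ir$pair_rows, function(chi_op) {
      P <- Reduce(`+`, Map(`*`, chi_op, rep)) / order
      .orthonormal_rows(V %*% (P + t(P)) / 2, rank = mG)
    })
    return(out)
  }
  n2 <- nrow(V)
  for (oi in seq_along(rep)) {
    A <- t((V %*% t(rep[[oi]])) %*% t(V))
    c_ <- sum(diag(A)) / n2
    if (abs(c_) > 0.95) next
    if (max(abs(A + t(A) - 2 * c_ * diag(n2))) > 1e-6) next  # not a rotation
    s_ <- sqrt(max(1 - c_^2, 0))
    rem <- V
    u_rows <- NULL; w_rows <- NULL
    for (copy in seq_len(mG)) {
      u <- .orthonormal_rows(rem, rank = NULL)[1, , drop = FALSE]
      tu <- u %*% t(rep[[oi]])
      w <- (tu - c_ * u) / s_
      u_rows <- rbind(u_rows, u); w_rows <- rbind(w_rows, w)
      rem <- rem - (rem %*% t(u)) %*% u - (rem %*% t(w)) %*% w
    }
    return(list(u_rows, w_rows))
  }
  stop("no rotation-type operation splits the complex-pair components")
}

.embed_rows <- function(V, cols, nb) {
  out <- matrix(0, nrow(V), nb)
  out[, cols] <- V
  out
}

.frame_from_axis <- function(z) {
  z <- z / sqrt(sum(z^2))
  x <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- x - sum(x * z) * z; x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  cbind(x, y, z)
}

#' Irrep multiplicities of a concrete representation
#'
#' Reduction formula applied to the traces of explicit representation
#' matrices.
#'
#' @param table a \code{character_table}.
#' @param rep list of representation matrices per operation.
#' @return integer vector of multiplicities per irrep.
#' @export
irrep_span_rep <- function(table, rep) {
  tr <- vapply(rep, function(m) sum(diag(m)), 0)
  s <- vapply(table$irreps, `[[`, 0L, "s")
  m <- as.numeric(table$chi[, table$class_of_op, drop = FALSE] %*% tr) /
    (table$order * s)
  if (any(abs(m - round(m)) > 1e-6))
    stop("non-integer multiplicity in representation reduction")
  as.integer(round(m))
}

#' Stack all SALC rows into one coefficient matrix
#'
#' @param salcs a \code{salc_set}.
#' @return matrix (total rows x basis size) with attributes \code{irrep},
#'   \code{component}, \code{set}, \code{l} describing each row.
#' @export
salc_matrix <- function(salcs) {
  m <- do.call(rbind, lapply(salcs$spaces, `[[`, "coef"))
  rep_each <- vapply(salcs$spaces, function(s) nrow(s$coef), 0L)
  attr(m, "irrep") <- rep(vapply(salcs$spaces, `[[`, "", "irrep"), rep_each)
  attr(m, "component") <- rep(vapply(salcs$spaces, `[[`, 0L, "component"),
                              rep_each)
  attr(m, "set") <- rep(vapply(salcs$spaces, `[[`, 0L, "set"), rep_each)
  attr(m, "l") <- rep(vapply(salcs$spaces, `[[`, 0L, "l"), rep_each)
  m
}

#' Full-space matrix of one group operation over the declared basis
#'
#' Direct sum over (set, shell) blocks of the permutation-times-shell
#' matrices; used to verify block-diagonalisation.
#'
#' @param salcs a \code{salc_set}.
#' @param op_index operation index in \code{salcs$group$ops}.
#' @param tol_geom matching tolerance.
#' @return basis-size square orthogonal matrix.
#' @export
full_operation_rep <- function(salcs, op_index, tol_geom = 0.05) {
  basis <- salcs$basis; nb <- nrow(basis)
  out <- matrix(0, nb, nb)
  o <- salcs$group$ops[[op_index]]
  for (si in seq_along(salcs$sets)) {
    set <- salcs$sets[[si]]
    pts <- salcs$molecule$xyz[set, , drop = FALSE]
    p <- .op_permutes(o$matrix, pts, tol_geom)
    if (is.null(p)) stop("operation does not permute set ", si)
    slots <- unique(basis$slot[basis$atom %in% set])
    for (slot in slots) {
      rows <- which(basis$atom %in% set & basis$slot == slot)
      l <- basis$l[rows[1]]
      M <- operation_matrix(l, o)
      ns <- length(set)
      P <- matrix(0, ns, ns); P[cbind(p, seq_len(ns))] <- 1
      out[rows, rows] <- P %x% M
    }
  }
  out
}

#' @export
print.salc_set <- function(x, ...) {
  cat(sprintf("SALCs for %s: %d basis functions, %d spaces\n",
              x$group$label, nrow(x$basis), length(x$spaces)))
  for (s in x$spaces)
    cat(sprintf("  set %d  l=%d  %-6s comp %d/%d  (%d function%s)\n",
                s$set, s$l, s$irrep, s$component, s$dim, nrow(s$coef),
                if (nrow(s$coef) > 1) "s" else ""))
  invisible(x)
}
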