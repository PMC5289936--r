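# Point groups: Schoenflies labels, generation of the full operation set as
# exact matrices, multiplication table, conjugacy classes (with the
# real-character merging convention), orientation tags, subgroups and
# permutation representations.

#' Parse a Schoenflies label
#'
#' @param label e.g. \code{"C3v"}, \code{"D47d"}, \code{"Oh"}, \code{"S4"},
#'   \code{"Cinfv"}, \code{"Dinfh"}.
#' @return list with \code{family} (one of C, Cv, Ch, S, D, Dh, Dd, T, Td,
#'   Th, O, Oh, I, Ih, Cs, Ci, Cinfv, Dinfh, Kh) and \code{n} (axis order,
#'   \code{NA} for polyhedral/special labels).
#' @export
parse_schoenflies <- function(label) {
  lab <- as.character(label)[1]
  special <- c("Cs", "Ci", "T", "Td", "Th", "O", "Oh", "I", "Ih",
               "Cinfv", "Dinfh", "Kh")
  if (lab %in% special)
    return(list(family = lab, n = NA_integer_, label = lab))
  m <- regmatches(lab, regexec("^([CDS])([0-9]+)(v|h|d)?$", lab))[[1]]
  if (length(m) == 0) stop("cannot parse Schoenflies label '", lab, "'")
  n <- as.integer(m[3])
  fam <- paste0(m[2], m[4])
  if (!fam %in% c("C", "Cv", "Ch", "S", "D", "Dh", "Dd"))
    stop("unsupported family in label '", lab, "'")
  if (fam == "S") {
    if (n %% 2L == 1L)
      stop("odd S", n, " is the same group as C", n, "h; use that label")
    if (n == 2L) return(list(family = "Ci", n = NA_integer_, label = "Ci"))
  }
  if (n < 1L) stop("axis order must be >= 1")
  if (fam == "C" && n == 1L) return(list(family = "C1", n = 1L, label = "C1"))
  list(family = fam, n = n, label = lab)
}

.group_order <- function(family, n) {
  switch(family,
    C1 = 1L, Cs = 2L, Ci = 2L, C = n, Cv = 2L * n, Ch = 2L * n, S = n,
    D = 2L * n, Dh = 4L * n, Dd = 4L * n,
    T = 12L, Th = 24L, Td = 24L, O = 24L, Oh = 48L, I = 60L, Ih = 120L,
    stop("no finite order for family ", family))
}

# exact operation matrices for a label in the canonical frame
# (principal axis = z, reference vertical direction = x)
.generate_ops_canonical <- function(family, n) {
  E <- diag(3)
  rot <- function(k, ord) rotation_matrix(c(0, 0, 1), 2 * pi * k / ord)
  srot <- function(k, ord) {
    m <- improper_rotation_matrix(c(0, 0, 1), 2 * pi / ord)
    out <- diag(3); for (i in seq_len(k %% ord)) out <- m %*% out; out
  }
  c2p <- function(az) rotation_matrix(c(cos(az), sin(az), 0), pi)
  sigv <- function(az) reflection_matrix(c(-sin(az), cos(az), 0))  # plane at azimuth az
  sigh <- reflection_matrix(c(0, 0, 1))
  ops <- switch(family,
    C1 = list(E),
    Cs = list(E, sigh),
    Ci = list(E, -E),
    C  = lapply(0:(n - 1), rot, ord = n),
    Cv = c(lapply(0:(n - 1), rot, ord = n),
           lapply((0:(n - 1)) * pi / n, sigv)),
    Ch = {
      r <- lapply(0:(n - 1), rot, ord = n)
      c(r, lapply(r, function(m) sigh %*% m))
    },
    S  = lapply(0:(n - 1), srot, ord = n),
    D  = c(lapply(0:(n - 1), rot, ord = n),
           lapply((0:(n - 1)) * pi / n, c2p)),
    Dh = {
      r <- c(lapply(0:(n - 1), rot, ord = n),
             lapply((0:(n - 1)) * pi / n, c2p))
      c(r, lapply(r, function(m) sigh %*% m))
    },
    Dd = c(lapply(0:(n - 1), rot, ord = n),
           lapply(seq(1, 2 * n - 1, by = 2), srot, ord = 2 * n),
           lapply((0:(n - 1)) * pi / n, c2p),
           lapply(pi / (2 * n) + (0:(n - 1)) * pi / n, sigv)),
    T  = .closure(list(rotation_matrix(c(0, 0, 1), pi),
                       rotation_matrix(c(1, 1, 1), 2 * pi / 3))),
    Td = .closure(list(rotation_matrix(c(0, 0, 1), pi),
                       rotation_matrix(c(1, 1, 1), 2 * pi / 3),
                       reflection_matrix(c(1, -1, 0)))),
    Th = .closure(list(rotation_matrix(c(0, 0, 1), pi),
                       rotation_matrix(c(1, 1, 1), 2 * pi / 3), -E)),
    O  = .closure(list(rotation_matrix(c(0, 0, 1), pi / 2),
                       rotation_matrix(c(1, 1, 1), 2 * pi / 3))),
    Oh = .closure(list(rotation_matrix(c(0, 0, 1), pi / 2),
                       rotation_matrix(c(1, 1, 1), 2 * pi / 3), -E)),
    I  = .closure(list(rotation_matrix(c(0, 0, 1), pi),
                       rotation_matrix(c(0, 1, (1 + sqrt(5)) / 2), 2 * pi / 5))),
    Ih = .closure(list(rotation_matrix(c(0, 0, 1), pi),
                       rotation_matrix(c(0, 1, (1 + sqrt(5)) / 2), 2 * pi / 5), -E)),
    stop("cannot generate operations for family ", family))
  ops
}

# group closure of a list of orthogonal matrices
.closure <- function(gens, tol = 1e-8, max_order = 1000L) {
  ops <- list(diag(3))
  keys <- new.env(parent = emptyenv())
  keyof <- function(m) paste(round(m, 6), collapse = ",")
  assign(keyof(diag(3)), 1L, envir = keys)
  addop <- function(m) {
    k <- keyof(m)
    if (!is.null(keys[[k]])) return(FALSE)
    # guard against rounding-boundary duplicates
    for (o in ops) if (max(abs(o - m)) < tol) return(FALSE)
    ops[[length(ops) + 1L]] <<- m
    assign(k, length(ops), envir = keys)
    TRUE
  }
  for (g in gens) addop(g)
  repeat {
    grew <- FALSE
    nn <- length(ops)
    for (i in seq_len(nn)) for (j in seq_len(nn)) {
      if (addop(ops[[i]] %*% ops[[j]])) grew <- TRUE
      if (length(ops) > max_order) stop("closure exceeded max_order")
    }
    if (!grew) break
  }
  ops
}

# orientation tag of an operation relative to a group frame.
# zax/xax: principal axis and reference vertical direction; n: principal order.
.orientation_tag <- function(op, zax, xax, n, family) {
  if (op$kind %in% c("identity", "inversion_centre")) return("none")
  a <- op$axis
  cz <- abs(sum(a * zax))
  if (op$kind == "mirror_plane") {
    if (cz > 1 - 1e-6) return("horizontal")
    if (cz > 1e-6) return("none")
    # in-plane normal: plane contains the principal axis
    if (is.na(n) || n < 2) return("vertical")
    yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
             zax[3] * xax[1] - zax[1] * xax[3],
             zax[1] * xax[2] - zax[2] * xax[1])
    az <- atan2(sum(a * yax), sum(a * xax))
    u <- (az - pi / 2) * n / pi   # plane azimuth in units of pi/n
    if (n %% 2L == 1L && !family %in% c("Dd"))
      return("vertical")
    k2 <- round(2 * u) %% (2 * n)
    if (k2 %% 2L == 1L) return("dihedral")
    if ((k2 / 2) %% 2L == 0L) "vertical" else
      if (family %in% c("Cv", "Dh")) "dihedral" else "vertical"
  } else if (op$kind == "proper_axis" && op$order == 2L && cz < 1e-6 &&
             !is.na(n) && n >= 2) {
    yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
             zax[3] * xax[1] - zax[1] * xax[3],
             zax[1] * xax[2] - zax[2] * xax[1])
    az <- atan2(sum(a * yax), sum(a * xax))
    u <- az * n / pi
    if (n %% 2L == 1L && !family %in% c("Dd")) return("vertical")
    k2 <- round(2 * u) %% (2 * n)
    if (k2 %% 2L == 1L) return("dihedral")
    if ((k2 / 2) %% 2L == 0L) "vertical" else
      if (family %in% c("Dh", "D")) "dihedral" else "vertical"
  } else "none"
}

# canonical sort key for operations: identity, proper rotations (descending
# order, principal axis first, then axis azimuth, then ascending power),
# improper rotations, mirrors (horizontal first, then by plane azimuth),
# inversion.
.op_sort_order <- function(ops, zax) {
  clean <- function(v) { v[abs(v) < 1e-9] <- 0; v }
  cat <- vapply(ops, function(o) switch(o$kind, identity = 0, proper_axis = 1,
                                        improper_axis = 2, mirror_plane = 3,
                                        inversion_centre = 4), 0)
  ord <- vapply(ops, function(o) o$order, 0L)
  pow <- vapply(ops, function(o) o$power, 0L)
  onz <- vapply(ops, function(o) -abs(sum(o$axis * zax)), 0)   # principal first
  a1 <- vapply(ops, function(o) {
    ax <- clean(o$axis)
    az <- atan2(ax[2], ax[1])
    if (o$kind == "mirror_plane") az <- az + pi / 2   # plane azimuth
    round(az %% pi, 9)
  }, 0)
  a2 <- vapply(ops, function(o) round(clean(o$axis)[3], 9), 0)
  order(cat, -ord, onz, a1, -a2, pow)
}

#' Generate the full operation set of a point group
#'
#' Emits all \eqn{|G|} operations as exact orthogonal matrices in an aligned
#' frame, with multiplication table, conjugacy classes (classes of mutually
#' inverse rotations merged, matching the real-character convention used for
#' real spherical harmonic bases), orientation tags and generators.
#'
#' @param label Schoenflies label (finite groups only).
#' @param align 3 x 3 orthogonal alignment transform; the canonical frame
#'   (principal axis z, reference vertical direction x) is mapped through it.
#' @return an object of class \code{"point_group"}: list with \code{label},
#'   \code{family}, \code{n}, \code{order}, \code{ops} (each with
#'   \code{matrix}, \code{kind}, \code{axis}, \code{order}, \code{power},
#'   \code{angle}, \code{orientation}, \code{class_id}), \code{classes},
#'   \code{mult_table}, \code{inverse}, \code{generators}, \code{zaxis},
#'   \code{xaxis}.
#' @export
point_group_from_label <- function(label, align = diag(3)) {
  p <- parse_schoenflies(label)
  if (p$family %in% c("Cinfv", "Dinfh"))
    stop("linear group '", label, "' has infinitely many operations; ",
         "use linear_group_table() for a finite surrogate")
  if (p$family == "Kh")
    stop("single-atom spherical symmetry is outside the finite-group machinery")
  mats <- .generate_ops_canonical(p$family, p$n)
  mats <- lapply(mats, function(m) align %*% m %*% t(align))
  maxo <- max(4L, 2L * (if (is.na(p$n)) 10L else p$n))
  ops <- lapply(mats, identify_operation, max_order = maxo)
  for (i in seq_along(ops)) ops[[i]]$matrix <- mats[[i]]
  zax <- align[, 3]; xax <- align[, 1]
  idx <- .op_sort_order(ops, zax)
  ops <- ops[idx]
  principal_n <- if (p$family %in% c("T", "Td", "Th", "O", "Oh", "I", "Ih"))
    NA_integer_ else p$n
  for (i in seq_along(ops))
    ops[[i]]$orientation <- .orientation_tag(ops[[i]], zax, xax,
                                             principal_n, p$family)
  g <- structure(list(label = p$label, family = p$family, n = p$n,
                      order = length(ops), ops = ops,
                      zaxis = zax, xaxis = xax, align = align),
                 class = "point_group")
  g$mult_table <- .mult_table(g)
  g$inverse <- apply(g$mult_table, 1, function(row) which(row == 1L)[1])
  g <- .assign_classes(g)
  g$generators <- .find_generators(g)
  g
}

.op_matrices <- function(group) lapply(group$ops, `[[`, "matrix")

# index of matrix m in the group's operation list (nearest within tol)
.match_op <- function(m, flat, tol = 1e-6) {
  d <- colSums(abs(flat - as.numeric(m)))
  j <- which.min(d)
  if (d[j] > tol * 9) NA_integer_ else j
}

.flat_ops <- function(group)
  vapply(group$ops, function(o) as.numeric(o$matrix), numeric(9))

.mult_table <- function(group) {
  n <- group$order
  flat <- .flat_ops(group)
  tab <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) {
    prods <- group$ops[[i]]$matrix %*% matrix(flat, 3)  # 3 x 3n block product
    pf <- matrix(0, 9, n)
    for (j in seq_len(n)) pf[, j] <- as.numeric(prods[, (3 * j - 2):(3 * j)])
    # nearest-op matching for the whole row at once
    d2 <- colSums(flat^2)
    cross <- crossprod(flat, pf)                         # n x n
    dist <- outer(d2, colSums(pf^2), "+") - 2 * cross
    row <- max.col(-t(dist))
    if (any(dist[cbind(row, seq_len(n))] > 1e-8))
      stop("group not closed under multiplication")
    tab[i, ] <- row
  }
  if (anyDuplicated(tab[1, ]) || anyDuplicated(tab[, 1]))
    stop("multiplication table is not a latin square")
  tab
}

# conjugacy classes with merging of mutually inverse classes
.assign_classes <- function(group) {
  n <- group$order
  tab <- group$mult_table; inv <- group$inverse
  cls <- rep(0L, n); ncls <- 0L
  for (i in seq_len(n)) {
    if (cls[i] != 0L) next
    ncls <- ncls + 1L
    orbit <- unique(vapply(seq_len(n), function(g) tab[tab[g, i], inv[g]], 0L))
    cls[orbit] <- ncls
    # real-character convention: the inverse class is merged in
    cls[inv[orbit]] <- ncls
  }
  # renumber in order of first appearance
  ids <- unique(cls)
  cls <- match(cls, ids)
  group$classes <- split(seq_len(n), cls)
  for (i in seq_len(n)) group$ops[[i]]$class_id <- cls[i]
  group
}

.find_generators <- function(group) {
  n <- group$order
  if (n == 1L) return(1L)
  tab <- group$mult_table
  span <- function(gen) {
    s <- c(1L, gen)
    repeat {
      s2 <- unique(as.integer(tab[s, s]))
      if (length(s2) == length(s)) return(s)
      s <- s2
    }
  }
  gens <- integer(0); cur <- 1L
  # greedy: prefer high-order proper rotations, then improper, then mirrors
  ord <- rev(.op_sort_order(group$ops, group$zaxis))
  cand <- setdiff(seq_len(n), 1L)
  cand <- cand[order(match(cand, rev(ord)))]
  covered <- 1L
  for (c_ in cand) {
    if (c_ %in% covered) next
    gens <- c(gens, c_)
    covered <- span(gens)
    if (length(covered) == n) break
  }
  gens
}

#' @export
print.point_group <- function(x, ...) {
  cat(sprintf("point group %s  (|G| = %d, %d classes)\n",
              x$label, x$order, length(x$classes)))
  invisible(x)
}

#' @export
summary.point_group <- function(object, ...) {
  cat(sprintf("point group %s, order %d\n", object$label, object$order))
  for (ci in seq_along(object$classes)) {
    ids <- object$classes[[ci]]
    o <- object$ops[[ids[1]]]
    cat(sprintf("  class %d: %d x %s\n", ci, length(ids), .op_name(o)))
  }
  invisible(object)
}

.op_name <- function(o) {
  switch(o$kind,
    identity = "E",
    inversion_centre = "i",
    mirror_plane = paste0("sigma",
      switch(o$orientation, horizontal = "_h", vertical = "_v",
             dihedral = "_d", "")),
    proper_axis = sprintf("C%d%s", o$order,
      if (o$power > 1) paste0("^", o$power) else ""),
    improper_axis = sprintf("S%d%s", o$order,
      if (o$power > 1) paste0("^", o$power) else ""))
}

# ---- permutations ----------------------------------------------------------

#' Permutation representation of a group action
#'
#' For a set of points, returns for each operation the permutation it induces
#' (image indices); for \code{ground = "self"}, the left regular action of
#' the group on its own operations, whose cycle structure is the canonical
#' non-trivial representation of the group.
#'
#' @param group a \code{point_group}.
#' @param ground N x 3 matrix of points mapped onto themselves by the group,
#'   or the string \code{"self"}.
#' @param tol geometric matching tolerance (Angstrom).
#' @return list of integer vectors \code{perm} (one per operation):
#'   \code{perm[j]} is the index of the image of point j.
#' @export
permutation_representation <- function(group, ground, tol = 0.05) {
  if (identical(ground, "self")) {
    return(lapply(seq_len(group$order), function(g) group$mult_table[g, ]))
  }
  pts <- matrix(as.numeric(ground), ncol = 3)
  lapply(group$ops, function(o) {
    im <- pts %*% t(o$matrix)
    p <- .match_points(im, pts, tol)
    if (anyNA(p))
      stop("operation ", .op_name(o), " does not map the ground set onto itself")
    p
  })
}

# nearest-neighbour matching of rows of a to rows of b; NA when no bijection.
# Near-coincident points (several targets within tol) are resolved by a
# greedy distance-ordered assignment.
.match_points <- function(a, b, tol) {
  n <- nrow(a)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  p <- max.col(-d2)
  bad <- d2[cbind(seq_len(n), p)] > tol^2
  if (any(bad)) return(rep(NA_integer_, n))
  if (!anyDuplicated(p)) return(p)
  cand <- which(d2 <= tol^2, arr.ind = TRUE)
  cand <- cand[order(d2[cand]), , drop = FALSE]
  p <- rep(NA_integer_, n); used <- logical(n)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (is.na(p[i]) && !used[j]) { p[i] <- j; used[j] <- TRUE }
  }
  if (anyNA(p)) return(rep(NA_integer_, n))
  p
}

#' Cycle decomposition of a permutation
#'
#' @param perm integer vector, \code{perm[j]} = image of j.
#' @return list of integer cycles (each starting at its smallest member),
#'   ordered by smallest member; fixed points included as singletons.
#' @export
permutation_cycles <- function(perm) {
  n <- length(perm)
  seen <- logical(n); out <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    cyc <- s; seen[s] <- TRUE; j <- perm[s]
    while (j != s) { cyc <- c(cyc, j); seen[j] <- TRUE; j <- perm[j] }
    out[[length(out) + 1L]] <- cyc
  }
  out
}

# ---- subgroups -------------------------------------------------------------

#' Enumerate all subgroups of a point group
#'
#' Exhaustive enumeration from the cyclic subgroups generated by the
#' permutation cycles of the multiplication table, closed under pairwise
#' joins until a fixed point.  All distinct subgroups are kept (no
#' deduplication up to conjugacy), because downstream partner-function
#' machinery needs concrete oriented subgroups.
#'
#' @param group a \code{point_group}.
#' @param max_order refuse groups larger than this (cost guard).
#' @return list of subgroups, each a list with \code{indices} (operation
#'   indices into \code{group$ops}, sorted, identity first), \code{order}
#'   and \code{label}; sorted by order then lexicographic indices.
#' @export
enumerate_subgroups <- function(group, max_order = 240L) {
  if (group$order > max_order)
    stop("group order ", group$order, " exceeds max_order = ", max_order)
  tab <- group$mult_table
  n <- group$order
  closure_idx <- function(s) {
    s <- sort(unique(as.integer(s)))
    repeat {
      s2 <- sort(unique(as.integer(tab[s, s])))
      if (length(s2) == length(s)) return(s2)
      s <- s2
    }
  }
  keyof <- function(s) paste(s, collapse = ".")
  subs <- new.env(parent = emptyenv())
  addsub <- function(s) {
    k <- keyof(s)
    if (is.null(subs[[k]])) { assign(k, s, envir = subs); TRUE } else FALSE
  }
  # cyclic subgroups from the powers (permutation cycles) of each operation
  for (g in seq_len(n)) {
    s <- 1L; x <- g
    while (x != 1L) { s <- c(s, x); x <- tab[x, g] }
    addsub(sort(unique(s)))
  }
  repeat {
    cur <- as.list(subs)
    grew <- FALSE
    lst <- unname(cur)
    for (i in seq_along(lst)) for (j in seq_along(lst)) {
      if (j <= i) next
      u <- closure_idx(c(lst[[i]], lst[[j]]))
      if (length(u) < n && addsub(u)) grew <- TRUE
    }
    if (!grew) break
  }
  addsub(seq_len(n))
  out <- unname(as.list(subs))
  ord <- vapply(out, length, 0L)
  out <- out[order(ord, vapply(out, function(s) paste(sprintf("%04d", s),
                                                      collapse = ""), ""))]
  lapply(out, function(s) {
    els <- lapply(group$ops[s], function(o)
      list(kind = o$kind, axis = o$axis, order = o$order))
    list(indices = s, order = length(s),
         label = determine_point_group(els))
  })
}

#' Expected subgroup count for families with a closed form
#'
#' Cyclic groups have d(n) subgroups; dihedral-type groups of rotation order
#' n have d(n) + sigma(n); polyhedral counts are fixed.  Returns \code{NA}
#' for families without a stored count.
#'
#' @param label Schoenflies label.
#' @return integer count or NA.
#' @export
expected_subgroup_count <- function(label) {
  p <- parse_schoenflies(label)
  divisors <- function(n) which(n %% seq_len(n) == 0L)
  if (p$family %in% c("C", "S")) {
    n <- if (p$family == "S") p$n else p$n
    return(length(divisors(n)))
  }
  if (p$family %in% c("Cv", "D")) {
    n <- p$n
    return(length(divisors(n)) + sum(divisors(n)))
  }
  fixed <- c(C1 = 1L, Cs = 2L, Ci = 2L, T = 10L, Td = 30L, Th = 26L,
             O = 30L, Oh = 98L, I = 59L, Ih = 164L)
  if (p$family %in% names(fixed)) return(unname(fixed[p$family]))
  NA_integer_
}

#' Extract a subgroup as a standalone point group object
#'
#' @param group parent \code{point_group}.
#' @param indices operation indices forming a subgroup.
#' @return a \code{point_group} for the subgroup in the parent's frame.
#' @export
subgroup_point_group <- function(group, indices) {
  indices <- sort(unique(as.integer(indices)))
  ops <- group$ops[indices]
  els <- lapply(ops, function(o) list(kind = o$kind, axis = o$axis,
                                      order = o$order))
  lab <- determine_point_group(els)
  p <- parse_schoenflies(lab)
  # subgroup frame: principal axis of the subgroup, reference vertical dir
  frame <- .frame_from_elements(els, p, group$zaxis, group$xaxis)
  g <- structure(list(label = lab, family = p$family, n = p$n,
                      order = length(ops), ops = ops,
                      zaxis = frame$z, xaxis = frame$x, align = frame$Q,
                      parent_indices = indices),
                 class = "point_group")
  g$mult_table <- .mult_table(g)
  g$inverse <- apply(g$mult_table, 1, function(row) which(row == 1L)[1])
  g <- .assign_classes(g)
  princ <- if (p$family %in% c("T", "Td", "Th", "O", "Oh", "I", "Ih"))
    NA_integer_ else p$n
  for (i in seq_along(g$ops))
    g$ops[[i]]$orientation <- .orientation_tag(g$ops[[i]], g$zaxis, g$xaxis,
                                               princ, p$family)
  g$generators <- .find_generators(g)
  g
}

# choose a (z, x) frame consistent with an element list
.frame_from_elements <- function(els, p, fallback_z, fallback_x) {
  kinds <- vapply(els, `[[`, "", "kind")
  orders <- vapply(els, function(e) e$order, 0L)
  z <- fallback_z
  if (p$family %in% c("Cs")) {
    z <- els[[which(kinds == "mirror_plane")[1]]]$axis
  } else if (any(kinds == "proper_axis")) {
    pmax_ <- max(orders[kinds == "proper_axis"])
    cand <- which(kinds == "proper_axis" & orders == pmax_)
    z <- els[[cand[1]]]$axis
  }
  # reference x: a vertical mirror normal x axis, a perpendicular C2, or any
  # perpendicular direction
  x <- NULL
  for (e in els) {
    if (e$kind == "proper_axis" && e$order == 2L &&
        abs(sum(e$axis * z)) < 1e-6) { x <- e$axis; break }
  }
  if (is.null(x)) for (e in els) {
    if (e$kind == "mirror_plane" && abs(sum(e$axis * z)) < 1e-6) {
      nrm <- e$axis
      x <- c(nrm[2] * z[3] - nrm[3] * z[2],
             nrm[3] * z[1] - nrm[1] * z[3],
             nrm[1] * z[2] - nrm[2] * z[1])   # in-plane direction
      break
    }
  }
  if (is.null(x)) x <- if (abs(sum(fallback_x * z)) < 0.9) fallback_x else
    c(0, 1, 0)
  x <- x - sum(x * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  list(z = z, x = x, Q = cbind(x, y, z))
}
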