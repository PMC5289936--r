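# Symmetry-element detection from equivalence-set geometry.
#
# Each equivalence set is analysed on its own: its inertial frame classifies
# it as linear-on-axis, axial or spherical (polyhedral).  Candidate elements
# are generated from the set geometry (ring azimuths about the principal
# axis; equidistant point pairs for polyhedral sets) and every candidate is
# validated against the set before it is reported.  The per-set element
# lists are then intersected, and the surviving elements symmetrised and
# aligned to the exact ideal geometry of the detected group.

# permutation induced by matrix m on points, or NULL when m is not a
# symmetry of the set within tol (Angstrom)
.op_permutes <- function(m, pts, tol) {
  im <- pts %*% t(m)
  # cheap prefilter: the image of the first point must land on some point
  d1 <- colSums((t(pts) - im[1, ])^2)
  if (min(d1) > tol^2) return(NULL)
  p <- .match_points(im, pts, tol)
  if (anyNA(p)) NULL else p
}

# least-squares refit of an approximate operation to the permutation it
# induces (orthogonal Procrustes, determinant sign preserved)
.refit_op <- function(m, pts, tol) {
  p <- .op_permutes(m, pts, tol)
  if (is.null(p)) return(m)
  B <- crossprod(pts, pts[p, , drop = FALSE])   # sum p_i q_i^T with q = image
  sv <- svd(B)
  R <- sv$v %*% t(sv$u)
  if (sign(det(R)) != sign(det(m))) {
    d <- diag(c(1, 1, -1))
    R <- sv$v %*% d %*% t(sv$u)
  }
  t(R)   # want R p_i ~ p_{perm(i)} with our row convention
}

# group 1-d values into clusters separated by more than tol
.group_values <- function(x, tol) {
  ord <- order(x)
  cl <- integer(length(x)); cur <- 1L
  cl[ord[1]] <- 1L
  for (k in seq_along(ord)[-1]) {
    if (x[ord[k]] - x[ord[k - 1]] > tol) cur <- cur + 1L
    cl[ord[k]] <- cur
  }
  cl
}

.divisors <- function(n) which(n %% seq_len(n) == 0L)

# deduplicate element records
.dedup_elements <- function(els, tol = 1e-4) {
  out <- list()
  for (e in els) {
    dup <- FALSE
    for (o in out) {
      if (o$kind == e$kind && o$order == e$order &&
          abs(sum(o$axis * e$axis)) > 1 - tol) { dup <- TRUE; break }
    }
    if (!dup) out[[length(out) + 1L]] <- e
  }
  out
}

#' Detect candidate symmetry elements of one equivalence set
#'
#' The set's own inertial pattern steers the search: a single atom at the
#' origin constrains nothing (wildcard); collinear-through-origin sets carry
#' an infinite-order axis; axial sets get ring-azimuth analysis about the
#' inertial axes; spherical (triply degenerate) sets go through the
#' polyhedral pair search.  Every reported element is validated: its matrix
#' permutes the set within \code{tol}.
#'
#' @param points k x 3 matrix of set positions (relative to the molecular
#'   centre of mass).
#' @param tol geometric validation tolerance (Angstrom).
#' @return object of class \code{"element_set"}: list with \code{elements}
#'   (validated finite elements; an infinite axis is encoded as a
#'   \code{proper_axis} of order 0), \code{cinf_axis} (unit vector or NULL),
#'   \code{wildcard} (TRUE for the unconstraining single-atom-at-origin
#'   case).
#' @export
detect_elements_for_set <- function(points, tol = 0.05) {
  pts <- matrix(as.numeric(points), ncol = 3)
  k <- nrow(pts)
  res <- function(elements, cinf = NULL, wildcard = FALSE)
    structure(list(elements = .dedup_elements(elements), cinf_axis = cinf,
                   wildcard = wildcard), class = "element_set")
  if (k == 1L && sqrt(sum(pts[1, ]^2)) < tol)
    return(res(list(), wildcard = TRUE))
  # collinear through the origin?
  sv <- svd(pts)
  if (k == 1L || sv$d[2] < tol) {
    v <- canonical_axis(sv$v[, 1])
    els <- list(sym_element("proper_axis", v, 0L))
    if (!is.null(.op_permutes(-diag(3), pts, tol))) {
      els <- c(els, list(sym_element("inversion_centre"),
                         sym_element("mirror_plane", v, 2L)))
    }
    return(res(els, cinf = v))
  }
  # degeneracy tolerance consistent with the geometric tolerance: atoms may
  # sit up to tol from their ideal positions, which shifts the moments by
  # about 2*tol/r_rms relative
  r_rms <- sqrt(mean(rowSums(pts^2)))
  deg_rel <- min(0.3, max(1e-4, 4 * tol / max(r_rms, tol)))
  frame <- inertial_frame(pts, rep(1, k), tol_deg = deg_rel)
  els0 <- list()
  axes <- lapply(1:3, function(j) frame$axes[, j])
  if (frame$class == "spherical") {
    els0 <- .detect_polyhedral_elements(pts, tol)
    am <- .axes_with_max_order(els0)
    if (sum(am$orders >= 3L) >= 2L) return(res(els0))
    # near-degenerate but not polyhedral: the eigenvectors are unreliable,
    # so continue with the axial search seeded by the axes found so far
    axes <- c(am$axes, axes)
  } else if (frame$class == "symmetric-top") {
    axes <- c(axes[frame$unique_axis], axes[-frame$unique_axis])
  }
  els <- els0
  seen_axis <- list()
  for (v in axes) {
    v <- canonical_axis(v)
    if (any(vapply(seen_axis, function(a) abs(sum(a * v)) > 1 - 1e-8, TRUE)))
      next
    seen_axis[[length(seen_axis) + 1L]] <- v
    els <- c(els, .axial_elements(pts, v, tol))
  }
  # inversion
  if (!is.null(.op_permutes(-diag(3), pts, tol)))
    els <- c(els, list(sym_element("inversion_centre")))
  res(els)
}

# validate a candidate matrix; on success refit it by Procrustes and return
# the refined axis (NULL otherwise).  The axis is read off the refitted
# matrix directly (no rational-angle reconstruction, so noisy geometry with
# slightly irrational refitted angles is fine).
.validated_axis <- function(m, pts, tol) {
  if (is.null(.op_permutes(m, pts, tol))) return(NULL)
  r <- .refit_op(m, pts, tol)
  if (det(r) < 0) r <- -r
  if (max(abs(r - diag(3))) < 1e-7) return(canonical_axis(m %*% c(0, 0, 1)))
  tr <- max(min((sum(diag(r)) - 1) / 2, 1), -1)
  .rotation_axis(r, acos(tr))
}

# elements about one candidate axis: principal rotations, sigma_h, S_m,
# perpendicular C2 family, vertical mirrors
.axial_elements <- function(pts, v, tol) {
  els <- list()
  h <- drop(pts %*% v)
  perp <- pts - outer(h, v)
  r <- sqrt(rowSums(perp^2))
  off <- which(r > tol)
  n <- 1L
  if (length(off) > 0L) {
    ring <- .group_values(h[off], tol) * 10000L + .group_values(r[off], tol)
    sizes <- table(ring)
    g <- Reduce(.gcd, as.integer(sizes))
    for (m in rev(.divisors(g))) {
      if (m < 2L) break
      ax <- .validated_axis(rotation_matrix(v, 2 * pi / m), pts, tol)
      if (!is.null(ax)) {
        n <- m
        v <- ax * sign(sum(ax * v) + 1e-300)   # refined principal axis
        h <- drop(pts %*% v); perp <- pts - outer(h, v)
        r <- sqrt(rowSums(perp^2)); off <- which(r > tol)
        break
      }
    }
    if (n >= 2L)
      for (d in .divisors(n)) if (d >= 2L)
        els <- c(els, list(sym_element("proper_axis", v, d)))
  } else {
    return(els)   # all points on this axis: handled by the collinear branch
  }
  if (!is.null(.op_permutes(reflection_matrix(v), pts, tol)))
    els <- c(els, list(sym_element("mirror_plane", v, 2L)))
  for (m in .divisors(2L * n)) {
    if (m < 4L || m %% 2L == 1L) next
    if (!is.null(.op_permutes(improper_rotation_matrix(v, 2 * pi / m), pts, tol)))
      els <- c(els, list(sym_element("improper_axis", v, m)))
  }
  # perpendicular C2 axes and vertical mirror planes: candidate azimuths are
  # the pairwise azimuth midpoints over a reference ring together with its
  # height-mirrored partner ring (a perpendicular C2 maps a point at (az, h)
  # to one at (2*alpha - az, -h), so its azimuth alpha bisects such pairs)
  ringid <- .group_values(h[off], tol) * 10000L + .group_values(r[off], tol)
  ref <- off[ringid == names(which.min(table(ringid)))[1]]
  if (length(ref) == 0L) ref <- off
  h_ref <- mean(h[ref]); r_ref <- mean(r[ref])
  partner <- off[abs(h[off] + h_ref) < tol & abs(r[off] - r_ref) < tol]
  sel <- unique(c(ref, partner))
  u1 <- perp[ref[1], ] / r[ref[1]]
  u2 <- c(v[2] * u1[3] - v[3] * u1[2], v[3] * u1[1] - v[1] * u1[3],
          v[1] * u1[2] - v[2] * u1[1])
  az <- atan2(drop(perp[sel, , drop = FALSE] %*% u2),
              drop(perp[sel, , drop = FALSE] %*% u1))
  mids <- outer(az, az, "+") / 2
  cand <- unique(round(c(mids[upper.tri(mids, diag = TRUE)]) %% pi, 8))
  for (a in cand) {
    u <- cos(a) * u1 + sin(a) * u2
    ax <- .validated_axis(rotation_matrix(u, pi), pts, tol)
    if (!is.null(ax))
      els <- c(els, list(sym_element("proper_axis", ax, 2L)))
    nrm <- c(v[2] * u[3] - v[3] * u[2], v[3] * u[1] - v[1] * u[3],
             v[1] * u[2] - v[2] * u[1])
    ax <- .validated_axis(reflection_matrix(nrm), pts, tol)
    if (!is.null(ax))
      els <- c(els, list(sym_element("mirror_plane", ax, 2L)))
  }
  els
}

#' Detect symmetry elements of a spherical-top (polyhedral) set
#'
#' Searches mirror, C2 and C4 operations between equidistant point pairs
#' (axes from pair sums, mirror normals from pair differences, plus the
#' point directions themselves and, for small sets, triple sums for C3
#' axes), validates each candidate, and generates the implied higher-order
#' elements by closing the validated operations under multiplication.
#'
#' @param points k x 3 matrix with a triply degenerate inertial pattern.
#' @param tol geometric validation tolerance (Angstrom).
#' @return list of validated symmetry elements.
#' @export
detect_polyhedral <- function(points, tol = 0.05) {
  pts <- matrix(as.numeric(points), ncol = 3)
  frame <- inertial_frame(pts, rep(1, nrow(pts)))
  if (frame$class != "spherical")
    stop("polyhedral search requires a triply degenerate inertial pattern")
  .dedup_elements(.detect_polyhedral_elements(pts, tol))
}

.detect_polyhedral_elements <- function(pts, tol) {
  k <- nrow(pts)
  cand_axes <- lapply(seq_len(k), function(i) pts[i, ])
  cand_norms <- list()
  pair <- utils::combn(k, 2L)
  for (c_ in seq_len(ncol(pair))) {
    i <- pair[1, c_]; j <- pair[2, c_]
    s <- pts[i, ] + pts[j, ]
    d <- pts[i, ] - pts[j, ]
    if (sqrt(sum(s^2)) > tol) cand_axes[[length(cand_axes) + 1L]] <- s
    if (sqrt(sum(d^2)) > tol) cand_norms[[length(cand_norms) + 1L]] <- d
  }
  if (k <= 30L) {
    trip <- utils::combn(k, 3L)
    for (c_ in seq_len(ncol(trip))) {
      s <- colSums(pts[trip[, c_], , drop = FALSE])
      if (sqrt(sum(s^2)) > tol) cand_axes[[length(cand_axes) + 1L]] <- s
    }
  }
  norm_dedup <- function(lst) {
    if (length(lst) == 0L) return(lst)
    kept <- matrix(0, length(lst), 3)
    nkept <- 0L
    for (v in lst) {
      u <- canonical_axis(v)
      if (nkept > 0L &&
          max(abs(kept[seq_len(nkept), , drop = FALSE] %*% u)) > 1 - 1e-7)
        next
      nkept <- nkept + 1L
      kept[nkept, ] <- u
    }
    lapply(seq_len(nkept), function(i) kept[i, ])
  }
  cand_axes <- norm_dedup(cand_axes)
  cand_norms <- norm_dedup(cand_norms)
  ops <- list()
  for (u in cand_axes) for (m in c(5L, 4L, 3L, 2L)) {
    R <- rotation_matrix(u, 2 * pi / m)
    if (!is.null(.op_permutes(R, pts, tol)))
      ops[[length(ops) + 1L]] <- .refit_op(R, pts, tol)
  }
  for (nrm in cand_norms) {
    M <- reflection_matrix(nrm)
    if (!is.null(.op_permutes(M, pts, tol)))
      ops[[length(ops) + 1L]] <- .refit_op(M, pts, tol)
  }
  if (!is.null(.op_permutes(-diag(3), pts, tol)))
    ops[[length(ops) + 1L]] <- -diag(3)
  if (length(ops) == 0L) return(list())
  closed <- .closure(ops, tol = 0.05, max_order = 200L)
  .elements_from_matrices(closed)
}

# extract the element list (with divisor orders for proper axes) from a set
# of operation matrices
.elements_from_matrices <- function(mats) {
  els <- list()
  best <- list()   # per (kind|axis) maximal order
  for (m in mats) {
    o <- identify_operation(m, max_order = 120L, angle_tol = 1e-3)
    if (o$kind == "identity") next
    if (o$kind == "inversion_centre") {
      els <- c(els, list(sym_element("inversion_centre"))); next
    }
    key <- paste(o$kind, paste(round(o$axis, 5), collapse = ","))
    cur <- best[[key]]
    if (is.null(cur) || o$order > cur$order)
      best[[key]] <- list(kind = o$kind, axis = o$axis, order = o$order)
  }
  for (b in best) {
    if (b$kind == "mirror_plane") {
      els <- c(els, list(sym_element("mirror_plane", b$axis, 2L)))
    } else if (b$kind == "proper_axis") {
      for (d in .divisors(b$order)) if (d >= 2L)
        els <- c(els, list(sym_element("proper_axis", b$axis, d)))
    } else {
      for (d in .divisors(b$order)) if (d >= 4L && d %% 2L == 0L)
        els <- c(els, list(sym_element("improper_axis", b$axis, d)))
    }
  }
  .dedup_elements(els)
}

#' Intersect per-set element lists
#'
#' Keeps only elements compatible with every equivalence set: matched
#' exactly (kind, order, axis within tolerance) against finite lists, with
#' the infinite-axis reduction rule: a set carrying a C-infinity axis admits
#' any finite rotation or improper rotation on that axis and any mirror
#' containing it (plus, when centrosymmetric, the horizontal mirror,
#' inversion and perpendicular C2 family), so intersection with a finite
#' C_n on the same axis yields the finite C_n.
#'
#' @param per_set_elements list of \code{"element_set"} objects (or plain
#'   element lists, treated as finite).
#' @param tol_axis angular tolerance (radians) for axis matching.
#' @return list of elements present in all sets (possibly empty = C1).
#' @export
intersect_element_sets <- function(per_set_elements, tol_axis = 1e-3) {
  descs <- lapply(per_set_elements, function(d) {
    if (inherits(d, "element_set")) d
    else structure(list(elements = d, cinf_axis = NULL, wildcard = FALSE),
                   class = "element_set")
  })
  descs <- Filter(function(d) !d$wildcard, descs)
  if (length(descs) == 0L) return(list())
  centro <- vapply(descs, function(d)
    any(vapply(d$elements, function(e) e$kind == "inversion_centre", TRUE)),
    TRUE)
  member <- function(e, d, cen) {
    if (!is.null(d$cinf_axis)) {
      a <- d$cinf_axis
      on_axis <- abs(sum(e$axis * a)) > cos(tol_axis)
      perp <- abs(sum(e$axis * a)) < sin(tol_axis)
      if (e$kind %in% c("proper_axis", "improper_axis") && on_axis) return(TRUE)
      if (e$kind == "mirror_plane" && perp) return(TRUE)
      if (cen) {
        if (e$kind == "inversion_centre") return(TRUE)
        if (e$kind == "mirror_plane" && on_axis) return(TRUE)
        if (e$kind == "proper_axis" && e$order == 2L && perp) return(TRUE)
      }
      if (e$kind == "proper_axis" && e$order == 0L) return(on_axis)
      return(FALSE)
    }
    for (o in d$elements) {
      if (o$kind != e$kind || o$order != e$order) next
      if (e$kind == "inversion_centre") return(TRUE)
      if (abs(sum(o$axis * e$axis)) > cos(tol_axis)) return(TRUE)
    }
    FALSE
  }
  pool <- .dedup_elements(unlist(lapply(descs, `[[`, "elements"),
                                 recursive = FALSE))
  keep <- Filter(function(e) all(vapply(seq_along(descs), function(i)
    member(e, descs[[i]], centro[i]), TRUE)), pool)
  keep
}
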