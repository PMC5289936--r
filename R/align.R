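# Symmetrisation of detected elements: replace the near-symmetric detected
# element geometry by the exact ideal geometry of the assigned group,
# aligned to the detected orientation by an orthogonal Procrustes fit over
# matched axis bundles.

# reduce a list of elements (possibly with divisor entries) to one record
# per (kind, axis) with the maximal order, plus the inversion flag
.reduce_elements <- function(els) {
  best <- list(); has_i <- FALSE
  for (e in els) {
    if (e$kind == "inversion_centre") { has_i <- TRUE; next }
    if (e$kind == "identity") next
    hit <- FALSE
    for (k in seq_along(best)) {
      b <- best[[k]]
      if (b$kind == e$kind && abs(sum(b$axis * e$axis)) > 1 - 1e-7) {
        if (e$order > b$order) best[[k]]$order <- e$order
        hit <- TRUE; break
      }
    }
    if (!hit) best[[length(best) + 1L]] <- e
  }
  list(elements = best, has_i = has_i)
}

.elements_of_group <- function(pg) {
  els <- lapply(pg$ops, function(o)
    list(kind = o$kind, axis = o$axis, order = o$order))
  .reduce_elements(els)
}

#' Symmetrise and align detected symmetry elements
#'
#' Constructs the exact ideal element geometry of \code{group_label} in the
#' canonical frame, finds the proper rotation best aligning it with the
#' detected elements (principal-axis pairing plus an orthogonal Procrustes
#' polish over matched axes), and returns the transformed ideal elements.
#' After symmetrisation all inter-element angles are exact.
#'
#' @param elements detected element list.
#' @param group_label Schoenflies label consistent with the elements.
#' @param max_residual largest tolerated angular mismatch (radians) between
#'   a detected axis and its ideal partner after alignment.
#' @return list with \code{elements} (ideal, transformed), \code{transform}
#'   (3 x 3 proper orthogonal), \code{residual} (radians).
#' @export
symmetrize_and_align <- function(elements, group_label, max_residual = 0.1) {
  p <- parse_schoenflies(group_label)
  if (p$family %in% c("C1", "Ci"))
    return(list(elements = elements, transform = diag(3), residual = 0))
  ideal_pg <- point_group_from_label(group_label)
  ideal <- .elements_of_group(ideal_pg)
  det_red <- .reduce_elements(elements)
  poly <- p$family %in% c("T", "Td", "Th", "O", "Oh", "I", "Ih")

  pick <- function(red, kind, order = NULL, perp_to = NULL, parallel_to = NULL) {
    for (e in red$elements) {
      if (e$kind != kind) next
      if (!is.null(order) && e$order != order) next
      if (!is.null(perp_to) && abs(sum(e$axis * perp_to)) > 1e-3) next
      if (!is.null(parallel_to) && abs(sum(e$axis * parallel_to)) < 1 - 1e-6)
        next
      return(e)
    }
    NULL
  }
  maxorder <- function(red) {
    o <- vapply(red$elements, function(e)
      if (e$kind == "proper_axis") e$order else 0L, 0L)
    if (length(o) == 0L) 0L else max(o)
  }

  if (p$family == "Cs") {
    d1 <- pick(det_red, "mirror_plane")$axis
    i1 <- c(0, 0, 1)
    d2 <- NULL; i2 <- NULL
  } else if (poly) {
    no <- maxorder(det_red)
    d1 <- pick(det_red, "proper_axis", no)$axis
    i1 <- pick(ideal, "proper_axis", no)$axis
    # secondary: another axis of some order at the matching inter-axis angle
    d2 <- i2 <- NULL
    for (e in det_red$elements) {
      if (e$kind != "proper_axis" || abs(sum(e$axis * d1)) > 1 - 1e-6) next
      ang_d <- acos(pmin(abs(sum(e$axis * d1)), 1))
      for (f in ideal$elements) {
        if (f$kind != "proper_axis" || f$order != e$order) next
        ang_i <- acos(pmin(abs(sum(f$axis * i1)), 1))
        if (abs(ang_d - ang_i) < 0.05 && ang_i > 1e-3) { d2 <- e$axis; i2 <- f$axis; break }
      }
      if (!is.null(d2)) break
    }
  } else {
    no <- maxorder(det_red)
    if (no < 2L) {
      so <- vapply(det_red$elements, function(e)
        if (e$kind == "improper_axis") e$order else 0L, 0L)
      d1 <- det_red$elements[[which.max(so)]]$axis
      i1 <- c(0, 0, 1)
    } else {
      d1 <- pick(det_red, "proper_axis", no)$axis
      i1 <- c(0, 0, 1)
    }
    c2 <- pick(det_red, "proper_axis", 2L, perp_to = d1)
    if (!is.null(c2) && p$family %in% c("D", "Dh", "Dd")) {
      d2 <- c2$axis; i2 <- c(1, 0, 0)
    } else {
      mir <- NULL
      for (e in det_red$elements)
        if (e$kind == "mirror_plane" && abs(sum(e$axis * d1)) < 1e-3) {
          mir <- e; break
        }
      if (!is.null(mir)) {
        d2 <- mir$axis
        im <- NULL
        for (f in ideal$elements)
          if (f$kind == "mirror_plane" && abs(sum(f$axis * c(0, 0, 1))) < 1e-6) {
            im <- f; break
          }
        i2 <- if (!is.null(im)) im$axis else NULL
        if (is.null(i2)) d2 <- NULL
      } else d2 <- i2 <- NULL
    }
  }

  frame_of <- function(z, x) {
    z <- z / sqrt(sum(z^2))
    if (is.null(x)) {
      x <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    }
    x <- x - sum(x * z) * z
    x <- x / sqrt(sum(x^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    cbind(x, y, z)
  }
  # angle between unit axes (sign-insensitive), accurate near zero where
  # acos of the dot product loses half the digits
  ang <- function(a, b) {
    if (sum(a * b) < 0) b <- -b
    2 * asin(min(1, sqrt(sum((a - b)^2)) / 2))
  }
  # every detected element must sit close to some transformed ideal element;
  # ideal elements without a detected partner are implied, not penalised
  score <- function(Q) {
    tot <- 0; cnt <- 0
    for (e in det_red$elements) {
      best <- pi / 2
      for (f in ideal$elements) {
        if (e$kind != f$kind || e$order != f$order) next
        a <- ang(drop(Q %*% f$axis), e$axis)
        if (a < best) best <- a
      }
      tot <- tot + best; cnt <- cnt + 1
    }
    if (cnt == 0) 0 else tot / cnt
  }
  cands <- list()
  for (s1 in c(1, -1)) {
    if (is.null(d2)) {
      cands[[length(cands) + 1L]] <- frame_of(s1 * d1, NULL) %*%
        t(frame_of(i1, NULL))
    } else for (s2 in c(1, -1)) {
      cands[[length(cands) + 1L]] <- frame_of(s1 * d1, s2 * d2) %*%
        t(frame_of(i1, i2))
    }
  }
  Q <- cands[[which.min(vapply(cands, score, 0))]]

  # Procrustes polish over detected axes matched to ideal partners
  for (iter in 1:2) {
    B <- matrix(0, 3, 3); matched <- 0L
    for (e in det_red$elements) {
      bi <- NULL; ba <- 0.3
      for (f in ideal$elements) {
        if (e$kind != f$kind || e$order != f$order) next
        a <- ang(drop(Q %*% f$axis), e$axis)
        if (a < ba) { ba <- a; bi <- f }
      }
      if (is.null(bi)) next
      t_ <- drop(Q %*% bi$axis)
      s <- sign(sum(t_ * e$axis)); if (s == 0) s <- 1
      B <- B + bi$axis %*% t(s * e$axis)
      matched <- matched + 1L
    }
    if (matched == 0L) break
    sv <- svd(B)
    R <- sv$v %*% t(sv$u)
    if (det(R) < 0) R <- sv$v %*% diag(c(1, 1, -1)) %*% t(sv$u)
    Q <- R
  }
  residual <- score(Q)
  if (residual > max_residual)
    stop(sprintf(
      "detected elements are inconsistent with %s (alignment residual %.3g rad)",
      group_label, residual))
  out <- lapply(ideal$elements, function(f)
    sym_element(f$kind, drop(Q %*% f$axis), f$order))
  if (ideal$has_i) out <- c(out, list(sym_element("inversion_centre")))
  list(elements = out, transform = Q, residual = residual)
}
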