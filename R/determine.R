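# Schoenflies classification from a validated symmetry-element list.

.axes_with_max_order <- function(elements, merge_tol = 0.02) {
  ax <- list(); ords <- integer(0)
  for (e in elements) {
    if (e$kind != "proper_axis" || e$order < 2L) next
    hit <- FALSE
    for (i in seq_along(ax)) {
      if (abs(sum(ax[[i]] * e$axis)) > cos(merge_tol)) {
        ords[i] <- max(ords[i], e$order); hit <- TRUE; break
      }
    }
    if (!hit) { ax[[length(ax) + 1L]] <- e$axis; ords <- c(ords, e$order) }
  }
  list(axes = ax, orders = ords)
}

#' Determine the Schoenflies label from a symmetry-element list
#'
#' Standard decision procedure: linear groups are handled by the caller;
#' multiple axes of order >= 3 select a polyhedral family; otherwise the
#' principal axis plus the presence of perpendicular C2 axes, horizontal or
#' vertical mirrors, improper axes and the inversion centre walk the usual
#' tree.  A single vertical mirror (or single perpendicular C2) suffices:
#' the remaining ones are implied and generated later.
#'
#' @param elements list of symmetry elements (\code{kind}, \code{axis},
#'   \code{order}); an infinite-order axis is encoded as order 0.
#' @param axis_tol angular slack (radians) for parallel/perpendicular tests,
#'   so slightly tilted detected axes still classify.
#' @return Schoenflies label string (\code{"C1"} is the fallback).
#' @export
determine_point_group <- function(elements, axis_tol = 0.02) {
  if (length(elements) == 0L) return("C1")
  kinds <- vapply(elements, `[[`, "", "kind")
  has_i <- any(kinds == "inversion_centre")
  mirrors <- elements[kinds == "mirror_plane"]
  if (any(vapply(elements, function(e)
    e$kind == "proper_axis" && e$order == 0L, TRUE))) {
    return(if (has_i) "Dinfh" else "Cinfv")
  }
  am <- .axes_with_max_order(elements)
  high <- which(am$orders >= 3L)
  if (length(high) >= 2L) {
    top <- max(am$orders[high])
    if (top >= 5L) return(if (has_i) "Ih" else "I")
    if (top == 4L) return(if (has_i) "Oh" else "O")
    if (has_i) return("Th")
    return(if (length(mirrors) > 0L) "Td" else "T")
  }
  n <- if (length(am$orders) > 0L) max(am$orders) else 1L
  if (n >= 2L) {
    principal <- am$axes[[which.max(am$orders)]]
    cpar <- cos(axis_tol); cperp <- sin(axis_tol)
    perp_c2 <- any(vapply(elements, function(e)
      e$kind == "proper_axis" && e$order == 2L &&
        abs(sum(e$axis * principal)) < cperp, TRUE))
    sig_h <- any(vapply(mirrors, function(e)
      abs(sum(e$axis * principal)) > cpar, TRUE))
    sig_v <- any(vapply(mirrors, function(e)
      abs(sum(e$axis * principal)) < cperp, TRUE))
    s2n <- any(vapply(elements, function(e)
      e$kind == "improper_axis" && e$order == 2L * n &&
        abs(sum(e$axis * principal)) > cpar, TRUE))
    if (perp_c2) {
      if (sig_h) return(sprintf("D%dh", n))
      if (sig_v) return(sprintf("D%dd", n))
      return(sprintf("D%d", n))
    }
    if (sig_h) return(sprintf("C%dh", n))
    if (sig_v) return(sprintf("C%dv", n))
    if (s2n) return(sprintf("S%d", 2L * n))
    return(sprintf("C%d", n))
  }
  if (length(mirrors) > 0L) return("Cs")
  if (has_i) return("Ci")
  "C1"
}
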