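# Top-level point-group detection pipeline: equivalence sets -> per-set
# elements -> intersection -> Schoenflies label -> symmetrised, aligned
# group with validated operations.

#' Detect the point group of a molecule
#'
#' Partitions the atoms into equivalence sets, deduces candidate symmetry
#' elements from each set's geometry, intersects them across sets (each
#' surviving element is validated against every set), classifies the
#' result, symmetrises the element geometry and generates the full aligned
#' operation set.  There is no upper bound on the detectable axis order.
#'
#' @param mol a \code{\link{molecule}}.
#' @param tol_geom geometric validation tolerance (Angstrom): an operation
#'   matches when every atom maps within this distance of an equivalent atom.
#' @param rel_tol relative tolerance of the equivalence-set clustering.
#' @return a \code{point_group} (see \code{\link{point_group_from_label}})
#'   with additional fields \code{molecule} (centred), \code{sets}
#'   (equivalence sets), \code{detected_elements} and
#'   \code{alignment_residual}.  Linear molecules return a lightweight
#'   object labelled \code{"Cinfv"}/\code{"Dinfh"} with the molecular
#'   \code{axis}; a single atom returns label \code{"Kh"}.
#' @export
detect_point_group <- function(mol, tol_geom = 0.05, rel_tol = 0.1) {
  mol <- center_molecule(mol)
  n <- nrow(mol$xyz)
  if (n == 1L)
    return(structure(list(label = "Kh", family = "Kh", n = NA_integer_,
                          order = Inf, molecule = mol),
                     class = c("spherical_point_group", "point_group")))
  sets <- equivalence_sets(mol, rel_tol)
  frame <- inertial_frame(mol$xyz, mol$mass)
  if (frame$class == "linear") {
    axis <- canonical_axis(frame$axes[, 1])
    cen <- all(vapply(sets, function(s)
      !is.null(.op_permutes(-diag(3), mol$xyz[s, , drop = FALSE], tol_geom)),
      TRUE))
    lab <- if (cen) "Dinfh" else "Cinfv"
    return(structure(list(label = lab, family = lab, n = NA_integer_,
                          order = Inf, axis = axis, molecule = mol,
                          sets = sets),
                     class = c("linear_point_group", "point_group")))
  }
  per_set <- lapply(sets, function(s)
    detect_elements_for_set(mol$xyz[s, , drop = FALSE], tol_geom))
  elements <- .intersect_validated(per_set, sets, mol, tol_geom)
  label <- determine_point_group(elements)
  if (label == "C1") {
    g <- point_group_from_label("C1")
    g$molecule <- mol; g$sets <- sets
    g$detected_elements <- elements; g$alignment_residual <- 0
    return(g)
  }
  saa <- symmetrize_and_align(elements, label)
  g <- point_group_from_label(label, align = saa$transform)
  # mandatory validation: every operation permutes every equivalence set
  for (s in sets) {
    pts <- mol$xyz[s, , drop = FALSE]
    for (o in g$ops) {
      if (is.null(.op_permutes(o$matrix, pts, tol_geom)))
        stop("generated operation ", .op_name(o),
             " fails to permute an equivalence set; geometry is more broken ",
             "than tol_geom")
    }
  }
  g$molecule <- mol
  g$sets <- sets
  g$detected_elements <- saa$elements
  g$alignment_residual <- saa$residual
  g
}

# intersection with direct validation of finite candidates against every set
.intersect_validated <- function(per_set, sets, mol, tol_geom) {
  descs <- Filter(function(d) !d$wildcard, per_set)
  keep_sets <- sets[!vapply(per_set, `[[`, TRUE, "wildcard")]
  if (length(descs) == 0L) return(list())
  pool <- .dedup_elements(unlist(lapply(descs, `[[`, "elements"),
                                 recursive = FALSE))
  centro <- vapply(descs, function(d)
    any(vapply(d$elements, function(e) e$kind == "inversion_centre", TRUE)),
    TRUE)
  # a finite candidate survives a set iff its matrix permutes that set; this
  # realises the infinite-axis reduction rule automatically (any finite
  # rotation about a collinear set's axis permutes it)
  ok <- function(e, i) {
    pts <- mol$xyz[keep_sets[[i]], , drop = FALSE]
    m <- element_matrix(e)
    !is.null(.op_permutes(m, pts, tol_geom))
  }
  Filter(function(e) {
    if (e$kind == "proper_axis" && e$order == 0L) {
      # infinite axes survive only into the linear branch, handled upstream
      return(FALSE)
    }
    all(vapply(seq_along(descs), function(i) ok(e, i), TRUE))
  }, pool)
}
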