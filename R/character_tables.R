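# Auto-generated real character tables.
#
# Cyclic and dihedral families (Cn, Cnv, Cnh, S2n, Dn, Dnh, Dnd) of arbitrary
# order are generated from the structure of the group: every such group is a
# cyclic or dihedral core (over a proper or improper principal generator),
# optionally times a sigma_h or inversion factor.  All characters are real;
# one-dimensional representations with complex characters are merged pairwise
# into real two-dimensional rows (flagged \code{complex_pair}), and the
# conjugacy classes are merged correspondingly (see point_group_from_label).
#
# For complex-pair rows the endomorphism factor s = 2 enters the counting and
# orthogonality theorems: sum(dim^2 / s) = |G| and
# sum_c |c| chi chi' = s |G| delta.  Real rows have s = 1.
#
# Polyhedral tables (T, Td, Th, O, Oh, I, Ih) are static verified data;
# linear groups get finite surrogate tables (linear_group_table).

#' Character of a two-dimensional E-type irrep
#'
#' \eqn{\chi^{E_j}(C_n^k) = 2 \cos(j k \, 2\pi/n)}, where j is the
#' incremental index of the E irrep.
#'
#' @param j E-irrep index (>= 1).
#' @param n principal axis order.
#' @param k operation power.
#' @return real character value.
#' @export
e_character <- function(j, n, k) 2 * cos(j * k * 2 * pi / n)

# ---- structural templates --------------------------------------------------

# family structure: core order N, core generator proper/improper, vertical
# elements present?, product factor ("none", "sh", "i")
.family_structure <- function(family, n) {
  switch(family,
    C1 = list(N = 1L, vert = FALSE, factor = "none"),
    Cs = list(N = 1L, vert = FALSE, factor = "sh"),
    Ci = list(N = 1L, vert = FALSE, factor = "i"),
    C  = list(N = n, vert = FALSE, factor = "none"),
    S  = list(N = n, vert = FALSE, factor = "none"),   # label order = core order
    Cv = list(N = n, vert = TRUE, factor = "none"),
    D  = list(N = n, vert = TRUE, factor = "none"),
    Ch = list(N = n, vert = FALSE, factor = "sh"),
    Dh = list(N = n, vert = TRUE, factor = "sh"),
    Dd = if (n %% 2L == 0L) list(N = 2L * n, vert = TRUE, factor = "none")
         else list(N = n, vert = TRUE, factor = "i"),
    stop("no generated table for family ", family))
}

# descriptor of one operation within the family structure:
# list(h = 0/1 product-factor exponent, type = "rot"/"vert", m, v)
.op_descriptor <- function(op, st, zax, xax) {
  M <- op$matrix
  h <- 0L
  if (st$factor == "sh" && op$det < 0) { h <- 1L; M <- reflection_matrix(zax) %*% M }
  if (st$factor == "i"  && op$det < 0) { h <- 1L; M <- -M }
  o <- identify_operation(M, max_order = max(4L, 2L * st$N))
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  if (o$kind == "identity")
    return(list(h = h, type = "rot", m = 0L, v = NA_integer_))
  if (o$kind == "inversion_centre") {
    # only reachable for improper cores (S family): i = S_N^{N/2}
    return(list(h = h, type = "rot", m = as.integer(st$N / 2), v = NA_integer_))
  }
  onz <- abs(sum(o$axis * zax))
  if (onz > 1 - 1e-6) {
    ang <- if (o$kind %in% c("proper_axis", "improper_axis"))
      2 * pi * o$power / o$order else 0
    if (sum(o$axis * zax) < 0) ang <- -ang
    m <- as.integer(round((ang * st$N / (2 * pi)) %% st$N))
    return(list(h = h, type = "rot", m = m, v = NA_integer_))
  }
  # vertical element: perpendicular C2 axis or vertical mirror plane
  az <- if (o$kind == "mirror_plane") {
    atan2(sum(o$axis * yax), sum(o$axis * xax)) + pi / 2   # plane azimuth
  } else atan2(sum(o$axis * yax), sum(o$axis * xax))
  v <- as.integer(round((az / (pi / st$N)) %% (2 * st$N))) %% st$N
  list(h = h, type = "vert", m = NA_integer_, v = v)
}

# analytic irrep list for a core of order N (cyclic when vert = FALSE,
# dihedral when TRUE).  Returns list of irreps:
#   list(name, dim, e_index, b (principal sign exponent), sv (vertical sign),
#        complex_pair)
.core_irreps <- function(N, vert) {
  irr <- list()
  if (!vert) {
    irr[[1]] <- list(name = "A", dim = 1L, e_index = NA_integer_, b = 0L,
                     sv = NA, complex_pair = FALSE)
    if (N %% 2L == 0L && N > 1L)
      irr[[length(irr) + 1L]] <- list(name = "B", dim = 1L,
                                      e_index = NA_integer_, b = 1L, sv = NA,
                                      complex_pair = FALSE)
    jmax <- ceiling(N / 2) - 1L
    for (j in seq_len(max(jmax, 0L)))
      irr[[length(irr) + 1L]] <- list(name = paste0("E", j), dim = 2L,
                                      e_index = j, b = NA, sv = NA,
                                      complex_pair = TRUE)
  } else {
    irr[[1]] <- list(name = "A1", dim = 1L, e_index = NA_integer_, b = 0L,
                     sv = 1, complex_pair = FALSE)
    irr[[2]] <- list(name = "A2", dim = 1L, e_index = NA_integer_, b = 0L,
                     sv = -1, complex_pair = FALSE)
    if (N %% 2L == 0L && N > 1L) {
      irr[[3]] <- list(name = "B1", dim = 1L, e_index = NA_integer_, b = 1L,
                       sv = 1, complex_pair = FALSE)
      irr[[4]] <- list(name = "B2", dim = 1L, e_index = NA_integer_, b = 1L,
                       sv = -1, complex_pair = FALSE)
    }
    jmax <- ceiling(N / 2) - 1L
    for (j in seq_len(max(jmax, 0L)))
      irr[[length(irr) + 1L]] <- list(name = paste0("E", j), dim = 2L,
                                      e_index = j, b = NA, sv = NA,
                                      complex_pair = FALSE)
  }
  irr
}

# character of a core irrep on a descriptor (h handled by the caller)
.core_character <- function(ir, d, N) {
  if (d$type == "rot") {
    if (ir$dim == 1L) (-1)^(ir$b * d$m) else e_character(ir$e_index, N, d$m)
  } else {
    if (ir$dim == 1L) (-1)^(ir$b * d$v) * ir$sv else 0
  }
}

# Mulliken renaming once parity suffixes are known
.suffix_name <- function(base, parity, style) {
  if (style == "gu") paste0(base, ifelse(parity > 0, "g", "u"))
  else paste0(base, ifelse(parity > 0, "'", "''"))
}

#' Generate the character table of a point group
#'
#' Cyclic/dihedral families of any order are generated analytically;
#' polyhedral groups use static verified tables.  Columns are the group's
#' conjugacy classes in their computed order.
#'
#' @param group a \code{point_group}.
#' @return object of class \code{"character_table"}: list with \code{label},
#'   \code{order}, \code{class_size}, \code{class_name}, \code{irreps} (list
#'   with \code{name}, \code{dim}, \code{e_index}, \code{complex_pair},
#'   \code{s}), \code{chi} (irreps x classes), \code{class_of_op} (operation
#'   index -> column).
#' @export
generate_character_table <- function(group) {
  if (group$family %in% c("T", "Td", "Th", "O", "Oh", "I", "Ih"))
    return(.polyhedral_table(group))
  st <- .family_structure(group$family, group$n)
  class_of_op <- vapply(group$ops, `[[`, 0L, "class_id")
  ncls <- length(group$classes)
  reps <- vapply(group$classes, `[[`, 0L, 1L)
  descs <- lapply(group$ops[reps], .op_descriptor, st = st,
                  zax = group$zaxis, xax = group$xaxis)
  core <- .core_irreps(st$N, st$vert)
  irreps <- list(); chi <- NULL
  add_row <- function(ir, row) {
    irreps[[length(irreps) + 1L]] <<- ir
    chi <<- rbind(chi, row)
  }
  if (st$factor == "none") {
    for (ir in core) {
      row <- vapply(descs, function(d) .core_character(ir, d, st$N), 0)
      add_row(ir, row)
    }
  } else {
    # product with sigma_h (factor "sh") or inversion (factor "i")
    has_i <- st$factor == "i" ||
      (st$factor == "sh" && st$N %% 2L == 0L)
    style <- if (has_i) "gu" else "pp"
    for (par in c(1, -1)) for (ir in core) {
      row <- vapply(descs, function(d)
        .core_character(ir, d, st$N) * par^d$h, 0)
      # name by inversion character when i is present, else by sigma_h
      psign <- if (st$factor == "i" || !has_i) par else {
        # chi(i)/|chi|: i = sigma_h * C_N^{N/2}
        dI <- list(h = 1L, type = "rot", m = as.integer(st$N / 2),
                   v = NA_integer_)
        sign(.core_character(ir, dI, st$N) * par)
      }
      ir2 <- ir
      ir2$name <- .suffix_name(ir$name, psign, style)
      add_row(ir2, row)
    }
  }
  tab <- .finish_table(group, irreps, chi, class_of_op)
  if (group$family == "S")
    tab <- .order_by_parity(.rename_s_family(tab, group))
  if (st$factor != "none") tab <- .order_by_parity(tab)
  tab
}

# conventional row order: gerade/primed block before ungerade/double-primed
.order_by_parity <- function(tab) {
  nm <- vapply(tab$irreps, `[[`, "", "name")
  odd <- grepl("u$|''$", nm)
  ord <- order(odd)
  tab$irreps <- tab$irreps[ord]
  tab$chi <- tab$chi[ord, , drop = FALSE]
  tab
}

# S_2n groups containing the inversion get g/u names (n/2 odd)
.rename_s_family <- function(tab, group) {
  iop <- which(vapply(group$ops, function(o) o$kind == "inversion_centre",
                      TRUE))
  if (length(iop) == 0L) return(tab)
  ci <- tab$class_of_op[iop[1]]
  for (k in seq_along(tab$irreps)) {
    ir <- tab$irreps[[k]]
    par <- sign(tab$chi[k, ci])
    base <- if (ir$dim == 1L) "A" else
      if (ceiling((group$n / 2 - 1) / 2) <= 1L) "E" else
        paste0("E", ceiling(ir$e_index / 2))
    tab$irreps[[k]]$name <- paste0(base, if (par > 0) "g" else "u")
  }
  rownames(tab$chi) <- vapply(tab$irreps, `[[`, "", "name")
  tab
}

.finish_table <- function(group, irreps, chi, class_of_op) {
  ncls <- length(group$classes)
  sizes <- vapply(group$classes, length, 0L)
  cnames <- vapply(seq_len(ncls), function(ci) {
    o <- group$ops[[group$classes[[ci]][1]]]
    paste0(if (sizes[ci] > 1) sizes[ci] else "", .op_name(o))
  }, "")
  # collapse duplicate names (single E etc.)
  nm <- vapply(irreps, `[[`, "", "name")
  e_only <- grepl("^E1($|g|u|'+)", nm) &
    !any(grepl("^E2", nm))
  nm[e_only] <- sub("^E1", "E", nm[e_only])
  for (i in seq_along(irreps)) irreps[[i]]$name <- nm[i]
  for (i in seq_along(irreps))
    irreps[[i]]$s <- if (isTRUE(irreps[[i]]$complex_pair)) 2L else 1L
  dimnames(chi) <- list(nm, cnames)
  structure(list(label = group$label, order = group$order,
                 class_size = sizes, class_name = cnames,
                 irreps = irreps, chi = chi, class_of_op = class_of_op),
            class = "character_table")
}

#' @export
print.character_table <- function(x, digits = 4, ...) {
  cat(sprintf("character table %s  (|G| = %d)\n", x$label, x$order))
  m <- round(x$chi, digits)
  print(m)
  invisible(x)
}

#' Validate the structural theorems of a character table
#'
#' Checks the dimension sum, row and column orthogonality (with the
#' endomorphism factor s = 2 for merged complex-pair rows), the totally
#' symmetric first row and the dimension first column.
#'
#' @param tab a \code{character_table}.
#' @param tol numeric tolerance.
#' @return TRUE invisibly; stops with a message on failure.
#' @export
validate_character_table <- function(tab, tol = 1e-10) {
  s <- vapply(tab$irreps, `[[`, 0L, "s")
  dims <- vapply(tab$irreps, `[[`, 0L, "dim")
  if (abs(sum(dims^2 / s) - tab$order) > tol)
    stop("dimension theorem fails for ", tab$label)
  nirr <- length(tab$irreps)
  for (i in seq_len(nirr)) for (j in seq_len(nirr)) {
    v <- sum(tab$class_size * tab$chi[i, ] * tab$chi[j, ])
    want <- if (i == j) s[i] * tab$order else 0
    if (abs(v - want) > tol * tab$order)
      stop(sprintf("row orthogonality fails for %s rows %d,%d", tab$label, i, j))
  }
  ncls <- ncol(tab$chi)
  for (a in seq_len(ncls)) for (b in seq_len(ncls)) {
    v <- sum(tab$chi[, a] * tab$chi[, b] / s)
    want <- if (a == b) tab$order / tab$class_size[a] else 0
    if (abs(v - want) > tol * tab$order)
      stop(sprintf("column orthogonality fails for %s cols %d,%d", tab$label, a, b))
  }
  if (any(abs(tab$chi[1, ] - 1) > tol))
    stop("first row is not totally symmetric for ", tab$label)
  identity_class <- tab$class_of_op[1]
  if (any(abs(tab$chi[, identity_class] - dims) > tol))
    stop("identity column does not list dimensions for ", tab$label)
  invisible(TRUE)
}

# ---- static polyhedral tables ---------------------------------------------

# class keys: kind / rounded |angle| (deg) / size
.poly_class_key <- function(op, size) {
  ang <- round(op$angle / pi * 180)
  ang <- min(ang, 360 - ang)
  kind <- switch(op$kind, identity = "E", inversion_centre = "i",
                 mirror_plane = "s", proper_axis = "C", improper_axis = "S")
  if (kind %in% c("E", "i", "s")) paste0(kind, ".", size)
  else paste0(kind, ang, ".", size)
}

.polyhedral_data <- function(family) {
  phi <- (1 + sqrt(5)) / 2
  switch(family,
    T = list(
      keys = c("E.1", "C120.8", "C180.3"),
      irreps = list(c("A", 1, 0), c("E", 2, 1), c("T", 3, 0)),
      chi = rbind(c(1, 1, 1), c(2, -1, 2), c(3, 0, -1))),
    Td = list(
      keys = c("E.1", "C120.8", "C180.3", "S90.6", "s.6"),
      irreps = list(c("A1", 1, 0), c("A2", 1, 0), c("E", 2, 0),
                    c("T1", 3, 0), c("T2", 3, 0)),
      chi = rbind(c(1, 1, 1, 1, 1), c(1, 1, 1, -1, -1), c(2, -1, 2, 0, 0),
                  c(3, 0, -1, 1, -1), c(3, 0, -1, -1, 1))),
    O = list(
      keys = c("E.1", "C120.8", "C180.6", "C90.6", "C180.3"),
      irreps = list(c("A1", 1, 0), c("A2", 1, 0), c("E", 2, 0),
                    c("T1", 3, 0), c("T2", 3, 0)),
      chi = rbind(c(1, 1, 1, 1, 1), c(1, 1, -1, -1, 1), c(2, -1, 0, 0, 2),
                  c(3, 0, -1, 1, -1), c(3, 0, 1, -1, -1))),
    Th = list(
      keys = c("E.1", "C120.8", "C180.3", "i.1", "S60.8", "s.3"),
      irreps = list(c("Ag", 1, 0), c("Eg", 2, 1), c("Tg", 3, 0),
                    c("Au", 1, 0), c("Eu", 2, 1), c("Tu", 3, 0)),
      chi = rbind(c(1, 1, 1, 1, 1, 1), c(2, -1, 2, 2, -1, 2),
                  c(3, 0, -1, 3, 0, -1), c(1, 1, 1, -1, -1, -1),
                  c(2, -1, 2, -2, 1, -2), c(3, 0, -1, -3, 0, 1))),
    Oh = list(
      keys = c("E.1", "C120.8", "C180.6", "C90.6", "C180.3",
               "i.1", "S60.8", "s.6", "S90.6", "s.3"),
      irreps = list(c("A1g", 1, 0), c("A2g", 1, 0), c("Eg", 2, 0),
                    c("T1g", 3, 0), c("T2g", 3, 0),
                    c("A1u", 1, 0), c("A2u", 1, 0), c("Eu", 2, 0),
                    c("T1u", 3, 0), c("T2u", 3, 0)),
      chi = {
        o <- rbind(c(1, 1, 1, 1, 1), c(1, 1, -1, -1, 1), c(2, -1, 0, 0, 2),
                   c(3, 0, -1, 1, -1), c(3, 0, 1, -1, -1))
        rbind(cbind(o, o), cbind(o, -o))
      }),
    I = list(
      keys = c("E.1", "C72.12", "C144.12", "C120.20", "C180.15"),
      irreps = list(c("A", 1, 0), c("T1", 3, 0), c("T2", 3, 0),
                    c("G", 4, 0), c("H", 5, 0)),
      chi = rbind(c(1, 1, 1, 1, 1),
                  c(3, phi, 1 - phi, 0, -1),
                  c(3, 1 - phi, phi, 0, -1),
                  c(4, -1, -1, 1, 0),
                  c(5, 0, 0, -1, 1))),
    Ih = list(
      # i C(72) = S(252) ~ S108 class; i C(144) = S(324) ~ S36 class
      keys = c("E.1", "C72.12", "C144.12", "C120.20", "C180.15",
               "i.1", "S108.12", "S36.12", "S60.20", "s.15"),
      irreps = list(c("Ag", 1, 0), c("T1g", 3, 0), c("T2g", 3, 0),
                    c("Gg", 4, 0), c("Hg", 5, 0),
                    c("Au", 1, 0), c("T1u", 3, 0), c("T2u", 3, 0),
                    c("Gu", 4, 0), c("Hu", 5, 0)),
      chi = {
        o <- rbind(c(1, 1, 1, 1, 1),
                   c(3, phi, 1 - phi, 0, -1),
                   c(3, 1 - phi, phi, 0, -1),
                   c(4, -1, -1, 1, 0),
                   c(5, 0, 0, -1, 1))
        rbind(cbind(o, o), cbind(o, -o))
      }),
    stop("no static table for ", family))
}

.polyhedral_table <- function(group) {
  dat <- .polyhedral_data(group$family)
  class_of_op <- vapply(group$ops, `[[`, 0L, "class_id")
  reps <- vapply(group$classes, `[[`, 0L, 1L)
  sizes <- vapply(group$classes, length, 0L)
  keys <- vapply(seq_along(reps), function(ci)
    .poly_class_key(group$ops[[reps[ci]]], sizes[ci]), "")
  col <- match(keys, dat$keys)
  if (anyNA(col))
    stop("cannot match classes of ", group$label, ": ",
         paste(keys[is.na(col)], collapse = " "))
  irreps <- lapply(dat$irreps, function(v)
    list(name = v[1], dim = as.integer(v[2]),
         e_index = NA_integer_,
         complex_pair = as.integer(v[3]) == 1L))
  chi <- dat$chi[, col, drop = FALSE]
  .finish_table(group, irreps, chi, class_of_op)
}

# ---- linear groups ---------------------------------------------------------

.linear_irrep_name <- function(j, suffix = "") {
  base <- if (j == 0) "Sigma" else
    c("Pi", "Delta", "Phi", "Gamma")[min(j, 4)]
  if (j > 4) base <- paste0("M", j)
  paste0(base, suffix)
}

#' Surrogate group and character table for a linear molecule
#'
#' Linear groups have infinitely many operations; a finite surrogate
#' \eqn{C_{2\ell v}} (for \eqn{C_{\infty v}}) or \eqn{D_{2\ell h}} (for
#' \eqn{D_{\infty h}}) splits every function of angular momentum up to
#' \code{l_max} exactly as the true linear group does, once the vertical and
#' dihedral C2 and mirror operations are assigned to shared conjugacy
#' classes.  The boundary B1/B2 pairs merge into two-dimensional rows.
#'
#' @param label \code{"Cinfv"} or \code{"Dinfh"}.
#' @param l_max highest angular momentum the basis carries (>= 0).
#' @param align 3 x 3 alignment transform (principal axis = third column).
#' @return list with \code{group} (the finite surrogate
#'   \code{point_group}) and \code{table} (its merged
#'   \code{character_table} with linear-style irrep names).
#' @export
linear_group_table <- function(label, l_max = 1L, align = diag(3)) {
  stopifnot(label %in% c("Cinfv", "Dinfh"))
  l <- max(as.integer(l_max), 1L)
  n <- 2L * l
  sub <- if (label == "Cinfv") sprintf("C%dv", n) else sprintf("D%dh", n)
  g <- point_group_from_label(sub, align = align)
  tab <- generate_character_table(g)
  # merge vertical/dihedral classes pairwise
  reps <- vapply(g$classes, `[[`, 0L, 1L)
  is_vd <- vapply(seq_along(g$classes), function(ci) {
    o <- g$ops[[reps[ci]]]
    o$orientation %in% c("vertical", "dihedral") &&
      (o$kind == "mirror_plane" ||
         (o$kind == "proper_axis" && o$order == 2L &&
            abs(sum(o$axis * g$zaxis)) < 1e-6))
  }, TRUE)
  # partner of a v/d class: the other class of the same kind
  kindof <- vapply(seq_along(g$classes), function(ci)
    g$ops[[reps[ci]]]$kind, "")
  detof <- vapply(seq_along(g$classes), function(ci)
    g$ops[[reps[ci]]]$det, 0)
  merge_to <- seq_along(g$classes)
  for (k in unique(kindof[is_vd])) for (d in unique(detof[is_vd])) {
    grp <- which(is_vd & kindof == k & detof == d)
    if (length(grp) == 2L) merge_to[grp[2]] <- grp[1]
  }
  newid <- match(merge_to, unique(merge_to))
  # rows that distinguish merged classes (the B pairs) merge into E-type rows
  nm <- vapply(tab$irreps, `[[`, "", "name")
  keep <- rep(TRUE, length(nm)); rows <- list(); irreps <- list()
  bpair <- function(a, b) {
    i <- which(nm == a); j <- which(nm == b)
    if (length(i) == 1L && length(j) == 1L) list(i = i, j = j) else NULL
  }
  pairs <- list(bpair("B1", "B2"), bpair("B1g", "B2g"), bpair("B1u", "B2u"))
  pairs <- Filter(Negate(is.null), pairs)
  chi <- tab$chi
  for (p in pairs) {
    # keep the two constituent rows (per operation) so partner components
    # can still be separated by their 1-dim projectors
    tab$irreps[[p$i]]$pair_rows <- list(tab$chi[p$i, tab$class_of_op],
                                        tab$chi[p$j, tab$class_of_op])
    chi[p$i, ] <- chi[p$i, ] + chi[p$j, ]
    keep[p$j] <- FALSE
    tab$irreps[[p$i]]$dim <- 2L
    tab$irreps[[p$i]]$complex_pair <- TRUE
    tab$irreps[[p$i]]$s <- 2L
    tab$irreps[[p$i]]$e_index <- l
  }
  chi <- chi[keep, , drop = FALSE]
  irreps <- tab$irreps[keep]
  # collapse columns
  ucl <- unique(merge_to)
  chi2 <- chi[, ucl, drop = FALSE]
  sizes <- vapply(seq_along(ucl), function(a)
    sum(tab$class_size[merge_to == ucl[a]]), 0L)
  class_of_op <- newid[tab$class_of_op]
  # linear-style irrep names keyed by the E index (angular momentum proj.);
  # the Sigma +/- superscript follows the character under a vertical mirror
  sigv_class <- NULL
  for (a in seq_along(ucl)) {
    o <- g$ops[[g$classes[[ucl[a]]][1]]]
    if (o$kind == "mirror_plane" && o$orientation %in% c("vertical", "dihedral"))
      sigv_class <- a
  }
  for (i in seq_along(irreps)) {
    ir <- irreps[[i]]
    sfx <- if (label == "Dinfh") {
      if (grepl("g$", ir$name)) "g" else if (grepl("u$", ir$name)) "u" else ""
    } else ""
    if (ir$dim == 1L) {
      pm <- if (!is.null(sigv_class) && chi2[i, sigv_class] > 0) "+" else "-"
      irreps[[i]]$name <- paste0(.linear_irrep_name(0L, sfx), pm)
    } else {
      j <- if (is.na(ir$e_index)) l else ir$e_index
      irreps[[i]]$name <- .linear_irrep_name(j, sfx)
      irreps[[i]]$e_index <- j
    }
  }
  cnames <- vapply(seq_along(ucl), function(a) {
    o <- g$ops[[g$classes[[ucl[a]]][1]]]
    paste0(if (sizes[a] > 1) sizes[a] else "", .op_name(o))
  }, "")
  dimnames(chi2) <- list(vapply(irreps, `[[`, "", "name"), cnames)
  table <- structure(list(label = label, order = g$order,
                          class_size = sizes, class_name = cnames,
                          irreps = irreps, chi = chi2,
                          class_of_op = class_of_op,
                          surrogate_of = label, surrogate_n = n),
                     class = "character_table")
  list(group = g, table = table)
}

# per-operation character lookup
.chi_of_ops <- function(tab, irrep_index) {
  tab$chi[irrep_index, tab$class_of_op]
}
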