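# Real spherical harmonic basis machinery.
#
# Shells are real solid harmonics S_lm, m = -l..l, with the fixed phase
# convention in which the l = 1 shell is (y, z, x).  Rotation matrices in
# this basis are built by the iterative l-from-(l-1) recursion over the
# l = 1 seed (the U, V, W recurrence), including the corrected sign in the
# V term; improper operations pick up the parity factor (-1)^l.

#' Evaluate real solid harmonics at cartesian points
#'
#' Direct recursive evaluation (diagonal and vertical recurrences), used as
#' an independent check of the rotation-matrix recursion.  Normalisation is
#' such that \eqn{S_{00} = 1} and the l = 1 shell is exactly (y, z, x).
#'
#' @param l angular momentum (>= 0).
#' @param xyz N x 3 matrix of points.
#' @return N x (2l+1) matrix, columns ordered m = -l..l.
#' @export
real_solid_harmonics <- function(l, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  r2 <- x^2 + y^2 + z^2
  n <- nrow(xyz)
  S <- vector("list", l + 1L)   # S[[k+1]] holds shell k as N x (2k+1)
  S[[1]] <- matrix(1, n, 1)
  if (l == 0L) return(S[[1]])
  S[[2]] <- cbind(y, z, x)
  if (l == 1L) return(S[[2]])
  for (k in 1:(l - 1L)) {
    cur <- S[[k + 1L]]; prev <- S[[k]]
    nxt <- matrix(0, n, 2L * (k + 1L) + 1L)
    colm <- function(mat, kk, m) mat[, m + kk + 1L]
    # diagonal recurrences
    f <- sqrt((2 * k + 1) / (2 * k + 2))
    nxt[, 2L * (k + 1L) + 1L] <- f * (x * colm(cur, k, k) - y * colm(cur, k, -k))
    nxt[, 1L] <- f * (y * colm(cur, k, k) + x * colm(cur, k, -k))
    # vertical recurrence for |m| <= k
    for (m in (-k):k) {
      a <- (2 * k + 1) * z * colm(cur, k, m)
      b <- if (abs(m) <= k - 1L) sqrt((k + m) * (k - m)) * r2 * colm(prev, k - 1L, m)
      else 0
      nxt[, m + k + 2L] <- (a - b) / sqrt((k + 1 + m) * (k + 1 - m))
    }
    S[[k + 2L]] <- nxt
  }
  S[[l + 1L]]
}

# l = 1 seed in the (y, z, x) basis: M1[a, b] = R[c_a, c_b], c = (2, 3, 1)
.seed_l1 <- function(rot) {
  c_ <- c(2L, 3L, 1L)
  rot[c_, c_]
}

#' Rotation matrix in the real spherical harmonic basis
#'
#' Builds the (2l+1) x (2l+1) orthogonal matrix representing a proper
#' rotation on the real shell of order l, by the iterative recursion from
#' the (l-1) matrix and the l = 1 seed.  The matrix M satisfies
#' \eqn{S_b(R^{-1} x) = \sum_a M_{ab} S_a(x)} and is homomorphic:
#' \eqn{M(R_1 R_2) = M(R_1) M(R_2)}.
#'
#' @param l angular momentum (>= 0).
#' @param rot proper orthogonal 3 x 3 matrix.
#' @return orthogonal (2l+1) x (2l+1) matrix, rows/columns ordered m = -l..l.
#' @export
rotation_matrix_real_sh <- function(l, rot) {
  if (abs(det(rot) - 1) > 1e-10) stop("expected a proper rotation (det = +1)")
  if (l == 0L) return(matrix(1, 1, 1))
  r <- .seed_l1(rot)
  if (l == 1L) return(r)
  M <- r
  for (ll in 2:l) M <- .sh_step(ll, r, M)
  M
}

# one step of the recursion: R^l from r (= R^1) and M (= R^(l-1))
.sh_step <- function(l, r, M) {
  idx1 <- function(i) i + 2L            # r index for i in -1..1
  idxM <- function(m) m + l             # M index for m in -(l-1)..(l-1)
  P <- function(i, mu, mp) {
    ri <- idx1(i)
    if (abs(mp) < l) {
      r[ri, idx1(0)] * M[idxM(mu), idxM(mp)]
    } else if (mp == l) {
      r[ri, idx1(1)] * M[idxM(mu), idxM(l - 1L)] -
        r[ri, idx1(-1)] * M[idxM(mu), idxM(-l + 1L)]
    } else {
      r[ri, idx1(1)] * M[idxM(mu), idxM(-l + 1L)] +
        r[ri, idx1(-1)] * M[idxM(mu), idxM(l - 1L)]
    }
  }
  out <- matrix(0, 2L * l + 1L, 2L * l + 1L)
  for (m in (-l):l) for (mp in (-l):l) {
    d <- if (abs(mp) < l) (l + mp) * (l - mp) else (2 * l) * (2 * l - 1)
    u <- sqrt((l + m) * (l - m) / d)
    v <- 0.5 * sqrt((1 + (m == 0)) * (l + abs(m) - 1) * (l + abs(m)) / d) *
      (1 - 2 * (m == 0))
    w <- -0.5 * sqrt((l - abs(m) - 1) * (l - abs(m)) / d) * (1 - (m == 0))
    acc <- 0
    if (u != 0) acc <- acc + u * P(0L, m, mp)
    if (v != 0) {
      acc <- acc + v * (
        if (m == 0) P(1L, 1L, mp) + P(-1L, -1L, mp)
        else if (m > 0) P(1L, m - 1L, mp) * sqrt(1 + (m == 1)) -
          P(-1L, -m + 1L, mp) * (1 - (m == 1))
        else P(1L, m + 1L, mp) * (1 - (m == -1)) +
          P(-1L, -m - 1L, mp) * sqrt(1 + (m == -1)))
    }
    if (w != 0) {
      acc <- acc + w * (
        if (m > 0) P(1L, m + 1L, mp) + P(-1L, -m - 1L, mp)
        else P(1L, m - 1L, mp) - P(-1L, -m + 1L, mp))
    }
    out[m + l + 1L, mp + l + 1L] <- acc
  }
  out
}

.sh_cache <- new.env(parent = emptyenv())

#' Matrix of an arbitrary symmetry operation on a real shell
#'
#' Proper operations use the rotation recursion; improper operations are the
#' rotation part of \eqn{-M} times the inversion parity \eqn{(-1)^l} (the
#' inversion acts as \eqn{(-1)^l} times the identity on a shell of order l).
#'
#' @param l angular momentum.
#' @param op a symmetry operation (list with \code{matrix}) or a 3 x 3
#'   orthogonal matrix.
#' @return (2l+1) x (2l+1) orthogonal matrix.
#' @export
operation_matrix <- function(l, op) {
  m <- if (is.list(op)) op$matrix else op
  key <- paste(l, paste(signif(as.numeric(m), 12), collapse = ","), sep = "|")
  hit <- .sh_cache[[key]]
  if (!is.null(hit)) return(hit)
  d <- det(m)
  out <- if (d > 0) rotation_matrix_real_sh(l, m)
  else (-1)^l * rotation_matrix_real_sh(l, -m)
  assign(key, out, envir = .sh_cache)
  out
}

#' Closed-form character of a symmetry operation on a real shell
#'
#' For a shell of order l (dimension |Y| = 2l+1):
#' proper rotations by angle t have
#' \eqn{\chi = \sin(t|Y|/2) / \sin(t/2)} (limit |Y| as t -> 0); improper
#' rotations \eqn{\chi = \cos(t|Y|/2) / \cos(t/2)} with the t -> pi limit
#' \eqn{(-1)^l |Y|} (the inversion) handled analytically; mirrors (t = 0)
#' give 1 for every l.
#'
#' @param l angular momentum.
#' @param op a symmetry operation (list with \code{matrix}, or an identified
#'   operation with \code{kind} and \code{angle}) or a 3 x 3 matrix.
#' @return real character value.
#' @export
sh_character <- function(l, op) {
  if (!is.list(op)) op <- identify_operation(op)
  if (is.null(op$kind)) op <- identify_operation(op$matrix)
  ny <- 2 * l + 1
  th <- op$angle
  if (op$kind == "identity") return(ny)
  if (op$kind == "inversion_centre") return((-1)^l * ny)
  if (op$kind == "mirror_plane") return(1)
  if (op$kind == "proper_axis") {
    s <- sin(th / 2)
    if (abs(s) < 1e-12) return(ny)
    return(sin(th * ny / 2) / s)
  }
  # improper rotation S(th); cos(th/2) = 0 only at th = pi (the inversion)
  c_ <- cos(th / 2)
  if (abs(c_) < 1e-12) return((-1)^l * ny)
  cos(th * ny / 2) / c_
}

#' Decompose a real shell over the irreps of a point group
#'
#' Applies the reduction formula
#' \eqn{m_\Gamma = (1/|G|) \sum_c |c| \chi^\Gamma(c) \chi^Y(c)} using only
#' the closed-form shell characters (no operation matrices needed); merged
#' complex-pair rows divide by their endomorphism factor so a pair counts
#' once.
#'
#' @param l angular momentum.
#' @param group a \code{point_group}.
#' @param table its \code{character_table}.
#' @param tol integrality tolerance.
#' @return named integer vector of multiplicities, one per irrep.
#' @export
irrep_span <- function(l, group, table, tol = 1e-8) {
  reps <- vapply(seq_along(table$class_size), function(ci)
    which(table$class_of_op == ci)[1], 0L)
  chiY <- vapply(group$ops[reps], function(o) sh_character(l, o), 0)
  s <- vapply(table$irreps, `[[`, 0L, "s")
  m <- as.numeric(table$chi %*% (table$class_size * chiY)) / (group$order * s)
  if (any(abs(m - round(m)) > tol))
    stop("non-integer irrep multiplicity; table and operations disagree")
  m <- as.integer(round(m))
  names(m) <- vapply(table$irreps, `[[`, "", "name")
  if (sum(m * vapply(table$irreps, `[[`, 0L, "dim")) != 2L * l + 1L)
    stop("irrep multiplicities do not sum to the shell dimension")
  m
}
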