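# Symmetry operations as 3x3 orthogonal matrices, plus extraction of the
# geometric element (kind, axis, order, power) from a matrix.

#' Rotation matrix about an axis
#'
#' @param axis length-3 vector (need not be normalised).
#' @param angle rotation angle in radians.
#' @return proper orthogonal 3 x 3 matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  c_ * diag(3) + s_ * ux + (1 - c_) * tcrossprod(u)
}

#' Reflection matrix through a plane containing the origin
#'
#' @param normal plane normal (need not be normalised).
#' @return orthogonal 3 x 3 matrix with determinant -1.
#' @export
reflection_matrix <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  diag(3) - 2 * tcrossprod(n)
}

#' Improper rotation (rotoreflection) matrix
#'
#' Rotation by \code{angle} about \code{axis} followed by reflection through
#' the plane perpendicular to it.
#'
#' @inheritParams rotation_matrix
#' @return orthogonal 3 x 3 matrix with determinant -1.
#' @export
improper_rotation_matrix <- function(axis, angle) {
  reflection_matrix(axis) %*% rotation_matrix(axis, angle)
}

# canonical sign: first component larger than tol in absolute value is positive
canonical_axis <- function(v, tol = 1e-8) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) return(c(0, 0, 1))
  v <- v / n
  j <- which(abs(v) > tol)[1]
  if (!is.na(j) && v[j] < 0) v <- -v
  v
}

# Build a symmetry-element record.  order 0 encodes an infinite-order axis.
sym_element <- function(kind, axis = c(0, 0, 1), order = 1L) {
  stopifnot(kind %in% c("proper_axis", "improper_axis", "mirror_plane",
                        "inversion_centre", "identity"))
  list(kind = kind, axis = canonical_axis(axis), order = as.integer(order))
}

# Rational reconstruction of t ~ k/n with n <= max_den; returns c(k, n) reduced.
.as_fraction <- function(t, max_den, tol = 1e-6) {
  t <- t %% 1
  for (n in 1:max_den) {
    k <- round(t * n)
    if (abs(t - k / n) < tol / n) {
      k <- k %% n
      if (k == 0) return(c(0L, 1L))
      g <- .gcd(k, n)
      return(c(as.integer(k / g), as.integer(n / g)))
    }
  }
  stop("rotation angle is not a small rational multiple of 2*pi")
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Identify the symmetry operation encoded by an orthogonal matrix
#'
#' Classifies a 3 x 3 orthogonal matrix as the identity, a proper rotation
#' \eqn{C_n^k}, a mirror plane, the inversion, or an improper rotation
#' \eqn{S_n^k}, recovering axis, order and power.
#'
#' @param m orthogonal 3 x 3 matrix.
#' @param max_order largest rotation order considered when reconstructing
#'   the rational rotation fraction.
#' @param angle_tol tolerance for the rational-angle reconstruction;
#'   loosen for operations refitted to noisy geometry.
#' @return list with \code{kind}, \code{axis}, \code{order}, \code{power},
#'   \code{angle} (radians in [0, 2pi)), \code{det}.
#' @export
identify_operation <- function(m, max_order = 400L, angle_tol = 1e-6) {
  d <- det(m)
  if (abs(abs(d) - 1) > 1e-8 || max(abs(crossprod(m) - diag(3))) > 1e-8)
    stop("matrix is not orthogonal")
  if (d > 0) {
    # acos near +1 amplifies rounding to ~sqrt(eps): test the matrix itself
    if (max(abs(m - diag(3))) < 1e-7)
      return(list(kind = "identity", axis = c(0, 0, 1), order = 1L,
                  power = 0L, angle = 0, det = 1))
    tr <- max(min((sum(diag(m)) - 1) / 2, 1), -1)
    theta <- acos(tr)
    axis <- .rotation_axis(m, theta)
    # signed angle w.r.t. canonical axis
    theta_s <- .signed_angle(m, axis)
    kn <- .as_fraction(theta_s / (2 * pi), max_order, angle_tol)
    list(kind = "proper_axis", axis = axis, order = kn[2], power = kn[1],
         angle = theta_s %% (2 * pi), det = 1)
  } else {
    # -m is a proper rotation by phi about axis b; m = S(b, phi - pi)
    if (max(abs(m + diag(3))) < 1e-7)    # m = -E
      return(list(kind = "inversion_centre", axis = c(0, 0, 1), order = 2L,
                  power = 1L, angle = pi, det = -1))
    r <- -m
    tr <- max(min((sum(diag(r)) - 1) / 2, 1), -1)
    phi <- acos(tr)
    axis <- .rotation_axis(r, phi)
    phi_s <- .signed_angle(r, axis)
    theta_s <- (phi_s - pi) %% (2 * pi)  # S-rotation angle
    if (min(theta_s, 2 * pi - theta_s) < max(1e-6, angle_tol))
      return(list(kind = "mirror_plane", axis = axis, order = 2L,
                  power = 1L, angle = 0, det = -1))
    kn <- .as_fraction(theta_s / (2 * pi), max_order, angle_tol)
    list(kind = "improper_axis", axis = axis, order = kn[2], power = kn[1],
         angle = theta_s, det = -1)
  }
}

# rotation axis of proper rotation m with angle theta in (0, pi]
.rotation_axis <- function(m, theta) {
  if (theta < pi - 1e-6) {
    v <- c(m[3, 2] - m[2, 3], m[1, 3] - m[3, 1], m[2, 1] - m[1, 2])
  } else {
    # theta ~ pi: axis from the +1 eigenvector of (m + I)/2
    a <- (m + diag(3)) / 2
    j <- which.max(diag(a))
    v <- a[, j]
  }
  canonical_axis(v)
}

# angle of proper rotation m measured about the (canonically signed) axis
.signed_angle <- function(m, axis) {
  # pick a vector perpendicular to axis
  p <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- p - sum(p * axis) * axis
  p <- p / sqrt(sum(p^2))
  q <- c(axis[2] * p[3] - axis[3] * p[2],
         axis[3] * p[1] - axis[1] * p[3],
         axis[1] * p[2] - axis[2] * p[1])
  mp <- m %*% p
  atan2(sum(mp * q), sum(mp * p)) %% (2 * pi)
}

#' Matrix of a symmetry element's generating operation
#'
#' @param el an element as returned by internal constructors: a list with
#'   \code{kind}, \code{axis}, \code{order}.
#' @param power power of the generator (default 1).
#' @return 3 x 3 orthogonal matrix.
#' @export
element_matrix <- function(el, power = 1L) {
  switch(el$kind,
    identity = diag(3),
    inversion_centre = -diag(3),
    mirror_plane = reflection_matrix(el$axis),
    proper_axis = rotation_matrix(el$axis, 2 * pi * power / el$order),
    improper_axis = {
      m1 <- improper_rotation_matrix(el$axis, 2 * pi / el$order)
      m <- diag(3); for (i in seq_len(power)) m <- m1 %*% m; m
    },
    stop("unknown element kind"))
}
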