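# Synthetic test-data supply: ideal symmetric molecules by orbit expansion,
# noise-perturbed variants, nanotube fixtures, and synthetic orbital sets.

#' Quasi-random general-position seed
#'
#' Deterministic low-discrepancy parameters (golden-ratio sequence) mapped
#' to a position in general position: irrational azimuth fraction, generic
#' radius and height, so the orbit of the seed has a trivial stabiliser.
#'
#' @param i seed index (>= 1).
#' @return length-3 position vector.
#' @export
general_position_seed <- function(i) {
  # azimuths 1.85 deg * i keep every seed azimuth and every pairwise
  # difference at least ~1.85 deg away from the k*90/n special-position
  # grids (mirror planes, dihedral planes, C2 axes) for n <= 12, so orbits
  # stay in general position and no accidental cross-orbit coincidences
  # arise at the default geometric tolerance
  az <- 1.85 * i * pi / 180
  r <- 0.9 + 0.27 * (i - 1) + 0.013 * sqrt(2) * i
  z <- 0.45 + 0.23 * (i - 1) + 0.011 * sqrt(3) * i
  c(r * cos(az), r * sin(az), z)
}

#' Generate an ideal (optionally noise-perturbed) symmetric molecule
#'
#' Applies every operation of the group to each seed, deduplicates
#' coincident images, optionally adds isotropic Gaussian noise, and
#' recentres.  With zero noise and general-position seeds, detection
#' recovers exactly the generating label.
#'
#' @param label Schoenflies label of a finite group.
#' @param seeds list of seeds, each a list with \code{element}, optional
#'   \code{position} (default: a \code{\link{general_position_seed}}) and
#'   optional \code{mass}; or NULL for two default seeds (C and N).
#' @param noise_sigma isotropic Gaussian noise s.d. (Angstrom).
#' @param rng_seed integer seed used when \code{noise_sigma > 0}.
#' @param align optional 3 x 3 alignment transform for the group.
#' @return a centred \code{\link{molecule}}.
#' @export
generate_symmetric_molecule <- function(label, seeds = NULL, noise_sigma = 0,
                                        rng_seed = 1L, align = diag(3)) {
  g <- point_group_from_label(label, align = align)
  if (is.null(seeds))
    seeds <- list(list(element = "C", position = general_position_seed(1)),
                  list(element = "N", position = general_position_seed(2)))
  element <- character(0); mass <- numeric(0)
  xyz <- matrix(0, 0, 3)
  for (s in seeds) {
    pos <- if (is.null(s$position)) general_position_seed(1) else s$position
    orbit <- t(vapply(g$ops, function(o) drop(o$matrix %*% pos), numeric(3)))
    keepers <- !duplicated(round(orbit, 8))
    orbit <- orbit[keepers, , drop = FALSE]
    element <- c(element, rep(s$element, nrow(orbit)))
    m <- if (is.null(s$mass)) atomic_mass(s$element) else s$mass
    mass <- c(mass, rep(m, nrow(orbit)))
    xyz <- rbind(xyz, orbit)
  }
  if (noise_sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(rng_seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sigma),
                        ncol = 3)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  center_molecule(molecule(element, xyz, mass,
                           comment = sprintf("synthetic %s orbit", label)))
}

#' Generate a staggered nanotube with exact D_nd symmetry
#'
#' A stack of antiprismatic rings: each seed sits on a dihedral mirror
#' plane, so its orbit under D_nd is a staggered pair of n-rings.
#' Construction guarantees the D_nd point group for generic radius/pitch.
#'
#' @param n rotational order (>= 2).
#' @param rings number of ring pairs (>= 1).
#' @param radius ring radius (Angstrom).
#' @param pitch vertical spacing between paired rings (Angstrom).
#' @param element element symbol.
#' @return a centred \code{\link{molecule}}.
#' @export
generate_nanotube <- function(n, rings = 2L, radius = 1.0, pitch = 0.9,
                              element = "C") {
  stopifnot(n >= 2L, rings >= 1L)
  az <- pi / (2 * n)   # special position on a sigma_d plane
  seeds <- lapply(seq_len(rings), function(j)
    list(element = element,
         position = c(radius * cos(az), radius * sin(az),
                      pitch * (j - 0.5) * (1 + 0.13 * (j - 1)))))
  generate_symmetric_molecule(sprintf("D%dd", n), seeds)
}

#' Generate synthetic orbitals from SALCs with cross-irrep contamination
#'
#' Each SALC row is mixed with a row of a different irrep so that the
#' contaminant carries the given squared-norm fraction; the ground-truth
#' assignment is recorded for recovery tests.
#'
#' @param salcs a SALC set as returned by \code{\link{build_salcs}}.
#' @param contamination squared-norm fraction (< 0.5) of the contaminant.
#' @param rng_seed integer seed for the choice of contaminant partners.
#' @return list with \code{coefficients} (orbitals x basis), \code{truth}
#'   (character vector of true irrep names) and \code{salc_row} (row index
#'   into the stacked SALC matrix).
#' @export
generate_test_orbitals <- function(salcs, contamination = 0, rng_seed = 1L) {
  stopifnot(contamination >= 0, contamination < 0.5)
  stack <- salc_matrix(salcs)
  irr <- attr(stack, "irrep")
  n <- nrow(stack)
  coef <- stack
  if (contamination > 0 && length(unique(irr)) > 1L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(rng_seed)
    for (i in seq_len(n)) {
      others <- which(irr != irr[i])
      j <- others[sample.int(length(others), 1L)]
      coef[i, ] <- sqrt(1 - contamination) * stack[i, ] +
        sqrt(contamination) * stack[j, ]
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  list(coefficients = coef, truth = irr, salc_row = seq_len(n))
}
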