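test_that("XYZ parsing handles the standard dialect and rejects bad input", {
  txt <- "3\nwater\nO 0 0 0\nH 0.76 0 -0.59\nH -0.76 0 -0.59\n"
  mol <- read_xyz(txt)
  expect_equal(mol$element, c("O", "H", "H"))
  expect_equal(mol$xyz[2, ], c(0.76, 0, -0.59))
  expect_equal(mol$mass[1], atomic_mass("O"))

  # optional 5th column overrides the mass (isotope-broken symmetry)
  iso <- read_xyz("1\nd\nH 0 0 0 2.014\n")
  expect_equal(iso$mass, 2.014)

  expect_error(read_xyz("0\nempty\n"), "count")
  expect_error(read_xyz("2\nc\nH 0 0 0\n"), "mismatch")
  expect_error(read_xyz("1\nc\nH a b c\n"), "non-numeric")
  expect_error(read_xyz("1\nc\nXx 0 0 0\n"), "unknown element")
})

test_that("write/read round trip preserves positions", {
  mol <- fix_ammonia()
  back <- read_xyz(write_xyz(mol))
  expect_equal(back$xyz, mol$xyz, tolerance = 1e-6)
  expect_equal(back$element, mol$element)
})

test_that("centre of mass is the mass-weighted mean", {
  m1 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 2)))
  expect_equal(center_of_mass(m1), c(0, 0, 1))
  m2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 3)),
                 mass = c(1, 2))
  expect_equal(center_of_mass(m2), c(0, 0, 2))
  m3 <- molecule("C", matrix(c(1, 2, 3), 1))
  expect_equal(center_of_mass(m3), c(1, 2, 3))
  cen <- center_molecule(fix_ferrocene())
  expect_lt(max(abs(crossprod(cen$xyz, cen$mass))), 1e-12)
})

test_that("inertial tensor matches closed forms", {
  expect_equal(inertial_tensor(matrix(0, 1, 3), 5), matrix(0, 3, 3))
  expect_equal(inertial_tensor(rbind(c(0, 0, 1), c(0, 0, -1)), c(1, 1)),
               diag(c(2, 2, 0)))
  # equilateral triangle, circumradius 1, xy-plane: sum of the three
  # rank-1 terms gives diag(3/2, 3/2, 3)
  a <- 2 * pi * (0:2) / 3
  tri <- cbind(cos(a), sin(a), 0)
  expect_equal(inertial_tensor(tri, rep(1, 3)), diag(c(1.5, 1.5, 3)))
  expect_error(inertial_tensor(tri, c(1, 1)), "mismatch")
})

test_that("trace identity: tr(I) = 2 sum m r^2", {
  set.seed(1)
  for (k in 1:20) {
    pts <- matrix(rnorm(15), 5, 3)
    m <- runif(5, 0.5, 20)
    expect_equal(sum(diag(inertial_tensor(pts, m))),
                 2 * sum(m * rowSums(pts^2)), tolerance = 1e-12)
  }
})

test_that("3x3 Jacobi solver is exact on closed-form cases", {
  e <- jacobi_eigen3(diag(3))
  expect_equal(e$values, c(1, 1, 1))
  e <- jacobi_eigen3(diag(c(3, 1, 2)))
  expect_equal(e$values, c(1, 2, 3))
  m <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 5), 3, 3)
  e <- jacobi_eigen3(m)   # characteristic roots 1, 3, 5
  expect_equal(e$values, c(1, 3, 5))
  expect_error(jacobi_eigen3(matrix(1:9, 3, 3)), "symmetric")
})

test_that("Jacobi agrees with the reference eigensolver and returns a
          right-handed orthonormal triad", {
  set.seed(7)
  worst <- 0
  for (k in 1:1000) {
    a <- matrix(rnorm(9), 3, 3)
    s <- a + t(a)
    e <- jacobi_eigen3(s)
    ref <- sort(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
    worst <- max(worst, max(abs(e$values - ref)) / max(abs(ref), 1))
    if (k <= 50) {
      expect_lt(max(abs(crossprod(e$vectors) - diag(3))), 1e-12)
      expect_gt(det(e$vectors), 0)
      expect_lt(max(abs(s %*% e$vectors -
                          e$vectors %*% diag(e$values))), 1e-9)
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("rigid rotation leaves the inertial moments invariant", {
  set.seed(11)
  pts <- matrix(rnorm(24), 8, 3)
  m <- runif(8, 1, 16)
  base <- jacobi_eigen3(inertial_tensor(pts, m))$values
  for (k in 1:10) {
    R <- random_rotation()
    rot <- jacobi_eigen3(inertial_tensor(pts %*% t(R), m))$values
    expect_equal(rot, base, tolerance = 1e-10)
  }
})

test_that("inertial frame classifies degeneracy patterns", {
  a <- 2 * pi * (0:2) / 3
  expect_equal(inertial_frame(rbind(c(0, 0, 1), c(0, 0, -1)),
                              c(1, 1))$class, "linear")
  expect_equal(inertial_frame(cbind(cos(a), sin(a), 0),
                              rep(1, 3))$class, "symmetric-top")
  td <- center_molecule(fix_methane())
  expect_equal(inertial_frame(td$xyz, td$mass)$class, "spherical")
  asym <- center_molecule(fix_water())
  expect_equal(inertial_frame(asym$xyz, asym$mass)$class, "asymmetric")
})
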