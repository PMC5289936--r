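test_that("geometry projection fixes symmetric input and recovers noisy
          input exactly", {
  mol <- fix_ammonia()
  g <- detect_point_group(mol)
  r0 <- symmetrize_molecule(mol, g)
  expect_lt(r0$error, 1e-10)
  expect_equal(r0$molecule$xyz, center_molecule(mol)$xyz, tolerance = 1e-10)

  set.seed(21)
  noisy <- mol
  noisy$xyz <- mol$xyz + matrix(rnorm(12, sd = 1e-3), 4, 3)
  gn <- detect_point_group(noisy)
  expect_equal(gn$label, "C3v")
  r <- symmetrize_molecule(noisy, gn)
  # exact invariance of the projected geometry
  X <- r$molecule$xyz
  for (o in gn$ops) {
    im <- X %*% t(o$matrix)
    p <- molsym:::.match_points(im, X, 0.05)
    expect_lt(max(abs(im - X[p, ])), 1e-12)
  }
  # error indicator on the scale of the injected noise
  expect_gt(r$error, 0)
  expect_lt(r$rms, 3e-3)
  # idempotency
  r2 <- symmetrize_molecule(r$molecule, gn)
  expect_lt(r2$error, 1e-10)
  expect_equal(r2$molecule$xyz, r$molecule$xyz, tolerance = 1e-12)
})

test_that("projection error equals the mass-weighted input-output distance", {
  set.seed(5)
  mol <- fix_water()
  noisy <- mol
  noisy$xyz <- mol$xyz + matrix(rnorm(9, sd = 2e-3), 3, 3)
  g <- detect_point_group(noisy)
  r <- symmetrize_molecule(noisy, g)
  cen <- center_molecule(noisy)
  d2 <- rowSums((cen$xyz - r$molecule$xyz)^2)
  expect_equal(r$error, sqrt(sum(cen$mass * d2)), tolerance = 1e-6)
})

test_that("orbital symmetry analysis gives exact fractions", {
  mol <- fix_ammonia()
  s <- build_salcs(mol, list(N = c(0, 1), H = 0L))
  C <- salc_matrix(s)
  irr <- attr(C, "irrep")
  rep <- analyze_orbital_symmetry(C, s)
  expect_equal(rep$irrep, irr)
  expect_equal(rep$fraction, rep(1, nrow(C)))
  # equal mixture of an A1 and an E SALC splits 0.5 / 0.5
  i1 <- which(irr == "A1")[1]
  i2 <- which(irr == "E")[1]
  mix <- (C[i1, ] + C[i2, ]) / sqrt(2)
  rep2 <- analyze_orbital_symmetry(matrix(mix, 1), s)
  fr <- attr(rep2, "fractions")
  expect_equal(unname(fr[1, c("A1", "E")]), c(0.5, 0.5), tolerance = 1e-10)
  # fractions always sum to one
  set.seed(8)
  Q <- qr.Q(qr(matrix(rnorm(nrow(C)^2), nrow(C))))
  rnd <- Q %*% C
  rep3 <- analyze_orbital_symmetry(rnd, s)
  expect_equal(rowSums(attr(rep3, "fractions")), rep(1, nrow(C)),
               tolerance = 1e-10)
})

test_that("wavefunction symmetrisation removes contamination and restores
          projector eigenfunctions", {
  mol <- fix_ammonia()
  s <- build_salcs(mol, list(N = c(0, 1), H = 0L))
  for (eps in c(0.01, 0.25, 0.49)) {
    to <- generate_test_orbitals(s, contamination = eps, rng_seed = 13)
    sw <- symmetrize_wavefunction(to$coefficients, s)
    expect_equal(sw$report$irrep, to$truth, info = paste("eps =", eps))
    expect_true(all(sw$report$final_fraction > 1 - 1e-8))
    # P^Gamma psi = psi and unit norms
    expect_equal(rowSums(sw$orbitals^2), rep(1, nrow(sw$orbitals)),
                 tolerance = 1e-9)
    for (ir in unique(sw$report$irrep)) {
      Tk <- do.call(rbind, molsym:::.irrep_stacks(s, ir))
      P <- crossprod(Tk)
      rows <- which(sw$report$irrep == ir)
      expect_lt(max(abs(sw$orbitals[rows, , drop = FALSE] %*% P -
                          sw$orbitals[rows, , drop = FALSE])), 1e-8)
    }
  }
  # already-adapted input comes back unchanged up to sign
  sw0 <- symmetrize_wavefunction(salc_matrix(s), s)
  agree <- abs(rowSums(sw0$orbitals * salc_matrix(s)))
  expect_equal(agree, rep(1, length(agree)), tolerance = 1e-9)
})

test_that("orbitals split 50/50 across irreps are rejected", {
  mol <- fix_ammonia()
  s <- build_salcs(mol, list(N = c(0, 1), H = 0L))
  C <- salc_matrix(s)
  irr <- attr(C, "irrep")
  mix <- (C[which(irr == "A1")[1], ] + C[which(irr == "E")[1], ]) / sqrt(2)
  expect_error(symmetrize_wavefunction(matrix(mix, 1), s),
               "symmetry broken")
})

test_that("symmetrised partner sets transform exactly into each other", {
  mol <- fix_ammonia()
  s <- build_salcs(mol, list(N = c(0, 1), H = 0L))
  to <- generate_test_orbitals(s, contamination = 0.1, rng_seed = 5)
  sw <- symmetrize_wavefunction(to$coefficients, s)
  C <- sw$orbitals
  irr <- sw$report$irrep
  for (oi in seq_len(s$group$order)) {
    D <- full_operation_rep(s, oi)
    T_ <- C %*% D %*% t(C)
    for (ir in unique(irr))
      expect_lt(max(abs(T_[irr == ir, irr != ir])), 1e-8)
  }
})
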