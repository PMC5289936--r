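test_that("weighted distance matrix has the reduced-mass form", {
  m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 2)), mass = c(1, 1))
  dm <- weighted_distance_matrix(center_molecule(m))
  expect_equal(dm[1, 2], 1.0)    # mu = 1/2, distance 2
  mol <- center_molecule(fix_ferrocene())
  dm <- weighted_distance_matrix(mol)
  expect_equal(unname(diag(dm)), rep(0, nrow(mol$xyz)))
  expect_identical(dm, t(dm))
})

test_that("invariant vectors are isometry invariant", {
  set.seed(3)
  mol <- center_molecule(fix_benzene())
  base <- molsym:::.invariant_matrix(mol)
  for (k in 1:10) {
    R <- random_rotation()
    rot <- mol
    rot$xyz <- mol$xyz %*% t(R)
    v <- molsym:::.invariant_matrix(rot)
    expect_equal(v, base, tolerance = 1e-9)
  }
  # atoms related by molecular symmetry share invariants exactly
  expect_lt(max(apply(base[1:6, ], 2, function(x) diff(range(x)))), 1e-9)
})

test_that("ferrocene plane projections vanish in D5d", {
  mol <- center_molecule(fix_ferrocene())
  v <- molsym:::.invariant_matrix(mol)
  expect_lt(max(v[, "plane_norm"]), 1e-9)
})

test_that("central atom and ligands of a tetrahedral XY4 differ in row mean", {
  mol <- center_molecule(fix_methane())
  v <- molsym:::.invariant_matrix(mol)
  expect_gt(abs(v[1, "row_mean"] - v[2, "row_mean"]),
            1e-3 * abs(v[2, "row_mean"]))
})

test_that("clustering groups orbits and keeps elements separate", {
  expect_equal(cluster_invariants(matrix(1, 5, 4)), list(1:5))
  sets <- equivalence_sets(fix_benzene())
  expect_equal(lapply(sets, sort), list(1:6, 7:12))
  sets <- equivalence_sets(fix_methane())
  expect_equal(lapply(sets, sort), list(1L, 2:5))
  # disjoint cover
  mol <- fix_ferrocene()
  sets <- equivalence_sets(mol)
  expect_equal(sort(unlist(sets)), seq_len(nrow(mol$xyz)))
  expect_equal(sum(lengths(sets)), nrow(mol$xyz))
})

test_that("refinement reaches a fixed point and only ever splits", {
  mol <- center_molecule(fix_benzene())
  stable <- equivalence_sets(mol)
  expect_identical(refine_partition(mol, stable), stable)

  # two concentric equal-mass rings accidentally merged: refinement splits
  # them once the diluting heavy atoms are out of the picture
  a <- 2 * pi * (0:5) / 6
  rings <- molecule(c(rep("C", 12), "Pb", "Pb"),
                    rbind(cbind(1.0 * cos(a), 1.0 * sin(a), 0),
                          cbind(1.3 * cos(a + 0.26), 1.3 * sin(a + 0.26), 0),
                          c(0, 0, 6), c(0, 0, -6)))
  rings <- center_molecule(rings)
  merged <- list(1:12, 13:14)
  refined <- refine_partition(rings, merged)
  expect_equal(lapply(refined, sort), list(1:6, 7:12, 13:14))
  # refinement property: every refined set is inside one input set
  for (s in refined)
    expect_true(any(vapply(merged, function(m) all(s %in% m), TRUE)))
})

test_that("multiset of invariants survives random proper rotations", {
  set.seed(5)
  mol <- center_molecule(fix_ammonia())
  base <- molsym:::.invariant_matrix(mol)
  base <- base[order(base[, 1], base[, 2]), ]
  for (k in 1:5) {
    R <- random_rotation()
    rot <- mol; rot$xyz <- mol$xyz %*% t(R)
    v <- molsym:::.invariant_matrix(rot)
    v <- v[order(v[, 1], v[, 2]), ]
    expect_equal(v, base, tolerance = 1e-9)
  }
})

test_that("the inertial-eigenvalue invariant partitions orbits too", {
  mol <- center_molecule(fix_benzene())
  v <- inertial_invariants(mol)
  expect_lt(max(apply(v[1:6, ], 2, function(x) diff(range(x)))), 1e-9)
  sets <- equivalence_sets(mol, invariant = "inertia")
  expect_equal(lapply(sets, sort), list(1:6, 7:12))
})
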