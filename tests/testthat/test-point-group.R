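test_that("Schoenflies labels parse and reject odd S", {
  expect_equal(parse_schoenflies("D47d")$n, 47L)
  expect_equal(parse_schoenflies("C3v")$family, "Cv")
  expect_equal(parse_schoenflies("S2")$family, "Ci")
  expect_error(parse_schoenflies("S5"), "C5h")
  expect_error(parse_schoenflies("Q3"), "parse")
})

test_that("generated groups have the right order, closure and inverses", {
  labs <- c("C1", "Cs", "Ci", "C4", "C4v", "C5h", "S6", "D4", "D5h", "D4d",
            "T", "Td", "Th", "O", "Oh", "I", "Ih")
  orders <- c(1, 2, 2, 4, 8, 10, 6, 8, 20, 16, 12, 24, 24, 24, 48, 60, 120)
  for (k in seq_along(labs)) {
    g <- point_group_from_label(labs[k])
    expect_equal(g$order, orders[k], info = labs[k])
    # closure and unique inverse are by-products of the latin multiplication
    # table; verify the matrices directly
    expect_equal(sort(g$mult_table[1, ]), seq_len(g$order), info = labs[k])
    expect_equal(length(unique(g$inverse)), g$order, info = labs[k])
    for (i in seq_len(min(g$order, 8))) {
      j <- g$inverse[i]
      expect_lt(max(abs(g$ops[[i]]$matrix %*% g$ops[[j]]$matrix - diag(3))),
                1e-12)
    }
    # class sizes sum to |G|; each class is a conjugacy class or a merged
    # pair of mutually inverse classes, so its size (or its half) divides |G|
    sizes <- unname(lengths(g$classes))
    expect_equal(sum(sizes), g$order, info = labs[k])
    expect_true(all(g$order %% sizes == 0 |
                      (sizes %% 2 == 0 & g$order %% (sizes / 2) == 0)),
                info = labs[k])
  }
})

test_that("operation matrices are orthogonal with the right determinant", {
  g <- point_group_from_label("D6h")
  for (o in g$ops) {
    expect_lt(max(abs(crossprod(o$matrix) - diag(3))), 1e-12)
    want <- if (o$kind %in% c("identity", "proper_axis")) 1 else -1
    expect_equal(det(o$matrix), want, tolerance = 1e-12)
  }
})

test_that("C3v has exactly E, 2C3, 3sigma_v and the printed regular action", {
  g <- point_group_from_label("C3v")
  nm <- vapply(g$ops, molsym:::.op_name, "")
  expect_equal(nm, c("E", "C3", "C3^2", "sigma_v", "sigma_v", "sigma_v"))
  perms <- permutation_representation(g, "self")
  # left regular action, cycle-for-cycle (sigma, sigma', sigma'' = the
  # mirrors in plane-azimuth order 0, 60, 120 degrees)
  expect_equal(perms[[2]], c(2L, 3L, 1L, 5L, 6L, 4L))  # C3
  expect_equal(perms[[3]], c(3L, 1L, 2L, 6L, 4L, 5L))  # C3^2
  expect_equal(perms[[4]], c(4L, 6L, 5L, 1L, 3L, 2L))  # sigma
  expect_equal(perms[[5]], c(5L, 4L, 6L, 2L, 1L, 3L))  # sigma'
  expect_equal(perms[[6]], c(6L, 5L, 4L, 3L, 2L, 1L))  # sigma''
  expect_equal(permutation_cycles(perms[[4]]),
               list(c(1L, 4L), c(2L, 6L), c(3L, 5L)))
  expect_equal(permutation_cycles(perms[[1]]), as.list(1:6))
})

test_that("point-group action on a geometry is a homomorphism", {
  g <- point_group_from_label("Td")
  mol <- center_molecule(fix_methane())
  perms <- permutation_representation(g, mol$xyz)
  tab <- g$mult_table
  for (i in seq_len(g$order)) for (j in c(1, 5, 9, 17)) {
    expect_equal(perms[[tab[i, j]]], perms[[i]][perms[[j]]])
  }
})

test_that("real-merging joins mutually inverse rotation classes", {
  g3 <- point_group_from_label("C3")
  expect_equal(unname(lengths(g3$classes)), c(1L, 2L))   # {E}, {C3, C3^2}
  g2v <- point_group_from_label("C2v")
  expect_equal(unname(lengths(g2v$classes)), rep(1L, 4))
  gI <- point_group_from_label("I")
  expect_equal(sort(unname(lengths(gI$classes))), c(1L, 12L, 12L, 15L, 20L))
})

test_that("mirror and perpendicular-axis orientation tags are assigned", {
  g <- point_group_from_label("D4h")
  mir <- Filter(function(o) o$kind == "mirror_plane", g$ops)
  tags <- vapply(mir, `[[`, "", "orientation")
  expect_equal(sum(tags == "horizontal"), 1L)
  expect_equal(sum(tags == "vertical"), 2L)
  expect_equal(sum(tags == "dihedral"), 2L)
  c2p <- Filter(function(o) o$kind == "proper_axis" && o$order == 2L &&
                  abs(o$axis[3]) < 1e-9, g$ops)
  expect_setequal(vapply(c2p, `[[`, "", "orientation"),
                  c("vertical", "dihedral"))
})

test_that("subgroup enumeration is exhaustive with the expected counts", {
  g <- point_group_from_label("C1")
  expect_equal(length(enumerate_subgroups(g)), 1L)
  subs <- enumerate_subgroups(point_group_from_label("C3v"))
  expect_equal(length(subs), 6L)
  expect_equal(sort(vapply(subs, `[[`, "", "label")),
               sort(c("C1", "Cs", "Cs", "Cs", "C3", "C3v")))
  # Lagrange
  for (s in subs) expect_equal(6L %% s$order, 0L)
  # closed-form counts: cyclic d(n); dihedral-type d(n) + sigma(n)
  expect_equal(length(enumerate_subgroups(point_group_from_label("C12"))),
               expected_subgroup_count("C12"))
  expect_equal(length(enumerate_subgroups(point_group_from_label("D6"))),
               expected_subgroup_count("D6"))
  expect_equal(length(enumerate_subgroups(point_group_from_label("C8v"))),
               expected_subgroup_count("C8v"))
  expect_equal(length(enumerate_subgroups(point_group_from_label("Td"))),
               expected_subgroup_count("Td"))
  expect_equal(length(enumerate_subgroups(point_group_from_label("Th"))),
               expected_subgroup_count("Th"))
})

test_that("decision tree walks the textbook leaves", {
  expect_equal(determine_point_group(list()), "C1")
  i_only <- list(list(kind = "inversion_centre", axis = c(0, 0, 1),
                      order = 2L))
  expect_equal(determine_point_group(i_only), "Ci")
  s_only <- list(list(kind = "mirror_plane", axis = c(0, 0, 1), order = 2L))
  expect_equal(determine_point_group(s_only), "Cs")
  # C3 axis plus a single vertical mirror suffices for C3v (the remaining
  # mirrors are implied)
  c3v <- list(list(kind = "proper_axis", axis = c(0, 0, 1), order = 3L),
              list(kind = "mirror_plane", axis = c(0, 1, 0), order = 2L))
  expect_equal(determine_point_group(c3v), "C3v")
  # a single perpendicular C2 suffices for the D family
  d3 <- list(list(kind = "proper_axis", axis = c(0, 0, 1), order = 3L),
             list(kind = "proper_axis", axis = c(1, 0, 0), order = 2L))
  expect_equal(determine_point_group(d3), "D3")
})
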