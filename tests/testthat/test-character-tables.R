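test_that("E-irrep characters follow 2 cos(jk 2pi/n)", {
  expect_equal(e_character(1, 7, 0), 2)
  expect_equal(e_character(1, 4, 1), 0, tolerance = 1e-12)
  expect_equal(e_character(2, 5, 1), 2 * cos(4 * pi / 5))
})

test_that("C2v and C3v tables are the textbook tables", {
  tab <- generate_character_table(point_group_from_label("C2v"))
  expect_equal(unname(tab$chi),
               rbind(c(1, 1, 1, 1), c(1, 1, -1, -1),
                     c(1, -1, 1, -1), c(1, -1, -1, 1)))
  expect_equal(rownames(tab$chi), c("A1", "A2", "B1", "B2"))

  tab <- generate_character_table(point_group_from_label("C3v"))
  expect_equal(unname(tab$chi),
               rbind(c(1, 1, 1), c(1, 1, -1), c(2, -1, 0)))
  expect_equal(rownames(tab$chi), c("A1", "A2", "E"))
  expect_equal(tab$class_size, c(1L, 2L, 3L), ignore_attr = TRUE)
})

test_that("all generated families n = 2..20 satisfy the table theorems", {
  fams <- c("C%d", "C%dv", "C%dh", "S%d", "D%d", "D%dh", "D%dd")
  for (f in fams) for (n in 2:20) {
    lab <- sprintf(f, if (f == "S%d") 2L * n else n)
    tab <- generate_character_table(point_group_from_label(lab))
    expect_no_error(validate_character_table(tab))
  }
  for (lab in c("C1", "Cs", "Ci", "T", "Td", "Th", "O", "Oh", "I", "Ih"))
    expect_no_error(
      validate_character_table(
        generate_character_table(point_group_from_label(lab))))
})

test_that("merged rows of cyclic groups are doubled real parts", {
  g <- point_group_from_label("C5")
  tab <- generate_character_table(g)
  # class representatives: E, C5, C5^2 (inverse-merged pairs)
  for (j in 1:2) {
    row <- tab$chi[paste0("E", j), ]
    expect_equal(unname(row), c(2, 2 * cos(2 * pi * j / 5),
                                2 * cos(4 * pi * j / 5)))
    expect_true(tab$irreps[[j + 1]]$complex_pair)
  }
})

test_that("characters match matrix traces in the real-SH representation", {
  for (lab in c("C4v", "D3d", "Td")) {
    g <- point_group_from_label(lab)
    tab <- generate_character_table(g)
    for (l in 1:2) {
      span <- irrep_span(l, g, tab)
      # reconstruct the shell character from the table and the span
      dims <- vapply(tab$irreps, `[[`, 0L, "dim")
      chiY <- as.numeric(span %*% tab$chi)
      reps <- vapply(seq_along(tab$class_size), function(ci)
        which(tab$class_of_op == ci)[1], 0L)
      direct <- vapply(g$ops[reps], function(o)
        sum(diag(operation_matrix(l, o))), 0)
      expect_equal(chiY, direct, tolerance = 1e-9)
    }
  }
})

test_that("linear surrogate tables split shells like the true linear group", {
  lg <- linear_group_table("Cinfv", l_max = 1)
  expect_no_error(validate_character_table(lg$table))
  m <- irrep_span(1, lg$group, lg$table)
  expect_equal(m[["Sigma+"]], 1L)   # p_z
  expect_equal(m[["Pi"]], 1L)       # (p_x, p_y) degenerate pair

  lg <- linear_group_table("Dinfh", l_max = 1)
  expect_no_error(validate_character_table(lg$table))
  m <- irrep_span(1, lg$group, lg$table)
  expect_equal(m[["Sigmau+"]], 1L)
  expect_equal(m[["Piu"]], 1L)      # Y_1m are u under inversion

  lg <- linear_group_table("Dinfh", l_max = 3)
  expect_no_error(validate_character_table(lg$table))
  m <- irrep_span(3, lg$group, lg$table)
  expect_equal(sum(m * vapply(lg$table$irreps, `[[`, 0L, "dim")), 7L)
})

test_that("static polyhedral tables carry golden-ratio icosahedral rows", {
  tab <- generate_character_table(point_group_from_label("Ih"))
  phi <- (1 + sqrt(5)) / 2
  t1g <- tab$chi["T1g", ]
  expect_equal(sort(unique(round(t1g, 10))),
               sort(unique(round(c(3, phi, 1 - phi, 0, -1), 10))))
  expect_equal(unname(tab$chi["Hg", tab$class_of_op[1]]), 5)
})
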