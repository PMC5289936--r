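test_that("direct product representation is the Kronecker homomorphism", {
  mol <- center_molecule(fix_h3())
  g <- detect_point_group(mol)
  perms <- permutation_representation(g, mol$xyz)
  for (l in 0:1) {
    mats <- lapply(g$ops, function(o) operation_matrix(l, o))
    rep <- direct_product_rep(perms, mats)
    for (i in seq_along(rep)) {
      p <- perms[[i]]
      expect_equal(sum(diag(rep[[i]])),
                   sum(p == seq_along(p)) * sum(diag(mats[[i]])),
                   tolerance = 1e-12)
    }
    tab <- g$mult_table
    expect_equal(rep[[tab[2, 4]]], rep[[2]] %*% rep[[4]], tolerance = 1e-12)
  }
})

test_that("trace projectors on three s-functions reproduce the hand sums", {
  mol <- center_molecule(fix_h3())
  g <- detect_point_group(mol)   # D3h for a bare triangle
  tab <- generate_character_table(g)
  perms <- permutation_representation(g, mol$xyz)
  rep <- direct_product_rep(perms, lapply(g$ops, function(o)
    operation_matrix(0, o)))
  P <- trace_projector(tab, "A1'", rep)
  expect_equal(P, matrix(1 / 3, 3, 3), tolerance = 1e-12)
  expect_equal(trace_projector(tab, "A2'", rep), matrix(0, 3, 3),
               tolerance = 1e-12)
  # completeness and idempotency
  tot <- Reduce(`+`, lapply(seq_along(tab$irreps), function(i)
    trace_projector(tab, i, rep)))
  expect_equal(tot, diag(3), tolerance = 1e-10)
  expect_equal(P %*% P, P, tolerance = 1e-12)
})

test_that("subspace extraction is deterministic and spans the image", {
  P <- matrix(1 / 3, 3, 3)
  B <- extract_subspace(P)
  expect_equal(B, matrix(1 / sqrt(3), 1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_null(extract_subspace(matrix(0, 3, 3)))
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:3]
  P <- tcrossprod(Q)
  B <- extract_subspace(P)
  expect_equal(nrow(B), 3L)
  expect_equal(B %*% P, B, tolerance = 1e-9)
  expect_equal(unname(tcrossprod(B)), diag(3), tolerance = 1e-10)
})

test_that("subduction of C3v reproduces the printed species", {
  g <- point_group_from_label("C3v")
  tab <- generate_character_table(g)
  subs <- enumerate_subgroups(g)
  labels <- vapply(subs, `[[`, "", "label")
  H <- subgroup_point_group(g, subs[[which(labels == "Cs")[1]]]$indices)
  tabH <- generate_character_table(H)
  expect_equal(subduce(tab, "A1", H, tabH), c("A'" = 1L, "A''" = 0L))
  expect_equal(subduce(tab, "A2", H, tabH), c("A'" = 0L, "A''" = 1L))
  expect_equal(subduce(tab, "E", H, tabH), c("A'" = 1L, "A''" = 1L))
  # down to C3 the E lands on the merged complex pair (e1 + e2)
  H3 <- subgroup_point_group(g, subs[[which(labels == "C3")[1]]]$indices)
  tabH3 <- generate_character_table(H3)
  m <- subduce(tab, "E", H3, tabH3)
  expect_equal(unname(m[["E"]]), 1L)
  expect_true(tabH3$irreps[[which(names(m) == "E")]]$complex_pair)
})

test_that("splitting subgroups avoid complex characters and chain for
          icosahedral irreps", {
  g <- point_group_from_label("C3v")
  tab <- generate_character_table(g)
  tr <- choose_splitting_subgroup(g, tab, "E")
  expect_equal(tr$subgroup$label, "Cs")
  expect_equal(vapply(tr$constituents, `[[`, "", "name"), c("A'", "A''"))

  gI <- point_group_from_label("I")
  tabI <- generate_character_table(gI)
  trH <- choose_splitting_subgroup(gI, tabI, "H")
  expect_equal(trH$subgroup$label, "D5")
  expect_equal(vapply(trH$constituents, `[[`, "", "name"),
               c("A1", "E1", "E2"))
  for (con in trH$constituents[2:3])
    expect_equal(con$tree$subgroup$label, "C2")
})

test_that("H3 s-basis SALCs are the textbook A1' + E' set", {
  mol <- fix_h3()
  s <- build_salcs(mol, list(H = 0L))
  C <- salc_matrix(s)
  expect_equal(nrow(C), 3L)
  irr <- attr(C, "irrep")
  expect_equal(sort(unique(irr)), c("A1'", "E'"))
  a1 <- C[irr == "A1'", ]
  expect_equal(abs(a1), rep(1 / sqrt(3), 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(tcrossprod(C), diag(3), tolerance = 1e-10)
})

test_that("a central atom's d shell in an Oh field splits into Eg + T2g", {
  at <- molecule("Cr", matrix(0, 1, 3))
  g <- point_group_from_label("Oh")
  g$sets <- list(1L)
  s <- build_salcs(at, list(Cr = 2L), g)
  irr <- vapply(s$spaces, `[[`, "", "irrep")
  expect_equal(sort(unique(irr)), c("Eg", "T2g"))
  expect_equal(sum(irr == "Eg"), 2L)    # two partner components
  expect_equal(sum(irr == "T2g"), 3L)
})

test_that("SALC rows block-diagonalise every operation (NH3, l <= 2)", {
  mol <- fix_ammonia()
  s <- build_salcs(mol, list(N = c(0, 1, 2), H = c(0, 1)))
  C <- salc_matrix(s)
  expect_equal(tcrossprod(C), diag(nrow(C)), tolerance = 1e-9)
  irr <- attr(C, "irrep")
  worst <- 0
  for (oi in seq_len(s$group$order)) {
    D <- full_operation_rep(s, oi)
    T_ <- C %*% D %*% t(C)
    for (ir in unique(irr)) worst <- max(worst,
      max(abs(T_[irr == ir, irr != ir])))
  }
  expect_lt(worst, 1e-8)
})

test_that("partner components transform identically across sets and shells", {
  mol <- fix_ammonia()
  s <- build_salcs(mol, list(N = c(0, 1, 2), H = c(0, 1)))
  esp <- Filter(function(x) x$dim == 2L, s$spaces)
  keys <- vapply(esp, function(x) paste(x$set, x$slot, x$l), "")
  gen <- 2L    # a C3 rotation
  D <- full_operation_rep(s, gen)
  actions <- list()
  for (k in unique(keys)) {
    pair <- esp[keys == k]
    mult <- nrow(pair[[1]]$coef)
    W <- rbind(pair[[1]]$coef, pair[[2]]$coef)
    A <- W %*% D %*% t(W)
    for (cp in seq_len(mult)) {
      idx <- c(cp, mult + cp)
      actions[[length(actions) + 1L]] <- A[idx, idx]
    }
  }
  for (a in actions[-1])
    expect_equal(a, actions[[1]], tolerance = 1e-8)
})

test_that("linear molecules split shells by angular momentum projection", {
  co2 <- molecule(c("C", "O", "O"),
                  rbind(c(0, 0, 0), c(0, 0, 1.16), c(0, 0, -1.16)))
  s <- build_salcs(co2, list(C = c(0, 1), O = c(0, 1)))
  C <- salc_matrix(s)
  cnt <- table(attr(C, "irrep"))
  expect_equal(cnt[["Sigmag+"]], 3L)
  expect_equal(cnt[["Sigmau+"]], 3L)
  expect_equal(cnt[["Piu"]], 4L)
  expect_equal(cnt[["Pig"]], 2L)
  expect_equal(tcrossprod(C), diag(nrow(C)), tolerance = 1e-9)
})

test_that("single-atom input refuses SALC construction", {
  at <- molecule("Ne", matrix(0, 1, 3))
  expect_error(build_salcs(at, list(Ne = c(0, 1))), "refused")
})

test_that("basis bookkeeping validates shell lists per set", {
  mol <- fix_h3()
  expect_error(build_salcs(mol, list(c(0L), c(0L, 1L), c(0L))),
               "different shell lists")
  bt <- basis_table(fix_water(), list(O = c(0, 1), H = 0))
  expect_equal(nrow(bt), 6L)
  expect_equal(bt$m[bt$atom == 1 & bt$l == 1], c(-1, 0, 1))
})
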