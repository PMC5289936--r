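el_count <- function(els, kind, order = NULL) {
  sum(vapply(els, function(e)
    e$kind == kind && (is.null(order) || e$order == order), TRUE))
}

test_that("a linear pair carries the infinite axis, sigma_h and inversion", {
  es <- detect_elements_for_set(rbind(c(0, 0, 1), c(0, 0, -1)))
  expect_false(es$wildcard)
  expect_equal(es$cinf_axis, c(0, 0, 1))
  expect_equal(el_count(es$elements, "inversion_centre"), 1L)
  expect_equal(el_count(es$elements, "mirror_plane"), 1L)
})

test_that("a single atom at the origin constrains nothing", {
  es <- detect_elements_for_set(matrix(0, 1, 3))
  expect_true(es$wildcard)
  expect_equal(length(es$elements), 0L)
})

test_that("a regular pentagon yields its full element set, all validated", {
  a <- 2 * pi * (0:4) / 5
  pent <- cbind(cos(a), sin(a), 0)
  es <- detect_elements_for_set(pent)
  els <- es$elements
  expect_equal(el_count(els, "proper_axis", 5L), 1L)
  expect_equal(el_count(els, "proper_axis", 2L), 5L)   # in-plane C2
  expect_equal(el_count(els, "mirror_plane"), 6L)      # 5 sigma_v + sigma_h
  # mandatory validation: every element permutes the set
  for (e in els) {
    m <- element_matrix(e)
    expect_false(is.null(molsym:::.op_permutes(m, pent, 1e-6)),
                 info = paste(e$kind, e$order))
  }
})

test_that("polyhedral pair search finds tetrahedral, octahedral and
          icosahedral axes", {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  els <- detect_polyhedral(tet)
  expect_equal(el_count(els, "proper_axis", 3L), 4L)
  expect_equal(el_count(els, "proper_axis", 2L), 3L)
  expect_equal(el_count(els, "improper_axis", 4L), 3L)
  expect_equal(el_count(els, "mirror_plane"), 6L)

  oct <- rbind(diag(3), -diag(3))
  els <- detect_polyhedral(oct)
  expect_equal(el_count(els, "proper_axis", 4L), 3L)
  expect_equal(el_count(els, "proper_axis", 3L), 4L)
  expect_equal(el_count(els, "mirror_plane"), 9L)
  expect_equal(el_count(els, "inversion_centre"), 1L)

  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
               c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
               c(phi, 0, 1), c(phi, 0, -1), c(-phi, 0, 1), c(-phi, 0, -1))
  els <- detect_polyhedral(ico)
  expect_equal(el_count(els, "proper_axis", 5L), 6L)
  expect_equal(el_count(els, "proper_axis", 3L), 10L)
  expect_error(detect_polyhedral(cbind(cos(2 * pi * (0:4) / 5),
                                       sin(2 * pi * (0:4) / 5), 0)),
               "triply degenerate")
})

test_that("intersection keeps shared elements and applies the infinite-axis
          reduction rule", {
  a <- 2 * pi * (0:4) / 5
  pent <- detect_elements_for_set(cbind(cos(a), sin(a), 0.4))
  ident <- intersect_element_sets(list(pent, pent))
  expect_equal(length(ident), length(pent$elements))
  pair <- detect_elements_for_set(rbind(c(0, 0, 1), c(0, 0, -1)))
  both <- intersect_element_sets(list(pair, pent))
  expect_equal(el_count(both, "proper_axis", 5L), 1L)   # Cinf reduced to C5
  expect_equal(el_count(both, "inversion_centre"), 0L)  # pentagon ring is not centrosymmetric about z=0.4
  # disjoint principal axes: only shared elements survive
  ring_z <- detect_elements_for_set(cbind(cos(a), sin(a), 0))
  b <- 2 * pi * (0:3) / 4
  ring_x <- detect_elements_for_set(cbind(rep(0, 4), cos(b), sin(b)))
  shared <- intersect_element_sets(list(ring_z, ring_x))
  expect_equal(el_count(shared, "proper_axis", 5L), 0L)
  expect_equal(el_count(shared, "proper_axis", 4L), 0L)
})

test_that("element symmetrisation restores exact geometry and is idempotent", {
  g <- point_group_from_label("C3v")
  ideal <- molsym:::.reduce_elements(lapply(g$ops, function(o)
    list(kind = o$kind, axis = o$axis, order = o$order)))$elements
  saa <- symmetrize_and_align(ideal, "C3v")
  expect_lt(saa$residual, 1e-10)
  expect_lt(max(abs(crossprod(saa$transform) - diag(3))), 1e-12)

  # tilt the C3 axis by 1e-4 rad; after symmetrisation the inter-element
  # angles are exact again
  tilt <- rotation_matrix(c(1, 0, 0), 1e-4)
  bent <- ideal
  bent[[1]]$axis <- drop(tilt %*% bent[[1]]$axis)   # the C3 axis
  saa2 <- symmetrize_and_align(bent, "C3v")
  ax <- NULL
  for (e in saa2$elements)
    if (e$kind == "proper_axis" && e$order == 3L) ax <- e$axis
  for (e in saa2$elements)
    if (e$kind == "mirror_plane")
      expect_equal(abs(sum(e$axis * ax)), 0, tolerance = 1e-12)
  # idempotency: re-symmetrising gives the same element set (possibly
  # relabelled by a symmetry of the set itself)
  saa3 <- symmetrize_and_align(saa2$elements, "C3v")
  expect_lt(saa3$residual, 1e-9)
  for (e in saa3$elements) {
    best <- min(vapply(saa2$elements, function(f)
      if (f$kind == e$kind && f$order == e$order)
        1 - abs(sum(f$axis * e$axis)) else 1, 0))
    expect_lt(best, 1e-12)
  }

  # inconsistent elements are rejected
  bad <- ideal
  bad[[1]]$axis <- drop(rotation_matrix(c(1, 0, 0), 0.5) %*% bad[[1]]$axis)
  expect_error(symmetrize_and_align(bad, "C3v"), "inconsistent")
})

test_that("order inference has no search-field ceiling (prism sweep)", {
  for (n in c(3, 5, 8, 13, 21, 34, 47, 50)) {
    a <- 2 * pi * (0:(n - 1)) / n
    prism <- rbind(cbind(cos(a), sin(a), 0.4), cbind(cos(a), sin(a), -0.4))
    es <- detect_elements_for_set(prism)
    ords <- vapply(es$elements, function(e)
      if (e$kind == "proper_axis") e$order else 0L, 0L)
    expect_equal(max(ords), n, info = paste("n =", n))
  }
})

test_that("products of symmetrised element matrices close under the group", {
  mol <- fix_ammonia()
  g <- detect_point_group(mol)
  flat <- vapply(g$ops, function(o) as.numeric(o$matrix), numeric(9))
  for (i in seq_len(g$order)) for (j in seq_len(g$order)) {
    prod <- g$ops[[i]]$matrix %*% g$ops[[j]]$matrix
    d <- min(colSums(abs(flat - as.numeric(prod))))
    expect_lt(d, 1e-10)
  }
})
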