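test_that("substitution effects reproduce the published worked example", {
  mw <- catalog_map("mouseweight")
  expect_equal(substitution_effects(mw, 1),
               c(3.66, -0.77, 1.77, 2.05, 2.71, 0.31))
  l1 <- locus_monotonicity(mw, 1)
  expect_equal(l1$P, 10.50)
  expect_equal(l1$N, 0.77)
  expect_equal(l1$T, 11.27)
  expect_equal(round(l1$m, 2), 0.86)
  l2 <- locus_monotonicity(mw, 2)
  expect_equal(l2$N, 1.42)
  expect_equal(l2$P, 8.37)
  expect_equal(l2$T, 9.79)
  expect_equal(round(l2$m, 2), 0.71)
  rep <- degree_of_monotonicity(mw)
  expect_equal(round(rep$m, 2), 0.79)
  expect_identical(rep$order_breaking_count, 2L)
  expect_false(is_monotone_locus(mw, 1))
  expect_false(is_monotone_locus(mw, 2))
})

test_that("additive and flat maps are the extreme cases", {
  a <- catalog_map("A")
  s <- substitution_effects(a, 1)
  expect_true(all(s == s[1]) && s[1] > 0)
  expect_equal(degree_of_monotonicity(a)$m, 1)

  flat <- gpmap(rep(2, 9))
  expect_true(all(substitution_effects(flat, 1) == 0))
  expect_warning(rep_flat <- degree_of_monotonicity(flat), "flat")
  expect_true(is.na(rep_flat$m))
  expect_true(rep_flat$flat)
  expect_identical(locus_monotonicity(flat, 1)$T, 0)

  for (nm in c("OD", "DxD", "AxA")) {
    expect_equal(degree_of_monotonicity(catalog_map(nm))$m, 0)
  }
})

test_that("mixed maps can be monotone for one locus only", {
  # monotone in locus 1, overdominant in locus 2
  cm <- counts_matrix(2)
  g <- gpmap(cm[, 1] + 0.5 * c(0, 1, 0)[cm[, 2] + 1])
  expect_true(is_monotone_locus(g, 1))
  expect_false(is_monotone_locus(g, 2))
  expect_identical(order_breaking_count(g), 1L)
})

test_that("m is invariant to allele relabelling and affine rescaling", {
  set.seed(21)
  for (rep in 1:200) {
    n <- sample(1:3, 1)
    g <- random_gpmap(n)
    m0 <- degree_of_monotonicity(g)$m
    flips <- runif(n) < 0.5
    expect_equal(degree_of_monotonicity(apply_orientation(g, flips))$m, m0)
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_equal(degree_of_monotonicity(gpmap(a * g$values + b, n))$m, m0)
    expect_lte(m0, 1)  # triangle-inequality bound
    expect_gte(m0, 0)
  }
})

test_that("m_k = 1 exactly when all non-zero effects share a sign", {
  set.seed(33)
  for (rep in 1:100) {
    g <- random_gpmap(2)
    r <- degree_of_monotonicity(g, orient = FALSE)
    for (k in 1:2) {
      s <- substitution_effects(g, k)
      single_sign <- all(s >= 0) || all(s <= 0)
      expect_identical(isTRUE(all.equal(r$per_locus$m[k], 1)), single_sign)
    }
    expect_identical(isTRUE(all.equal(r$m, 1)),
                     all(vapply(1:2, function(k) {
                       s <- substitution_effects(g, k)
                       all(s >= 0) || all(s <= 0)
                     }, TRUE)))
  }
})

test_that("order-breaking counts agree with the defining double loop", {
  set.seed(44)
  for (rep in 1:100) {
    g <- random_gpmap(sample(2:3, 1))
    flags <- brute_monotone_loci(g, zero_tol = default_zero_tol(g))
    expect_identical(order_breaking_count(g), sum(!flags))
    for (k in seq_len(g$n_loci)) {
      expect_identical(is_monotone_locus(g, k), flags[k])
      # the flag is allele-relabelling invariant
      flips <- runif(g$n_loci) < 0.5
      expect_identical(is_monotone_locus(apply_orientation(g, flips), k),
                       flags[k])
    }
  }
  # a consistently decreasing locus is monotone: relabelling its alleles
  # satisfies the chain inequalities in every background
  g <- gpmap(c(2, 1, 0, 3, 2, 1, 3, 2, 1))
  expect_true(is_monotone_locus(g, 2))
  expect_identical(order_breaking_count(g), 0L)
})

test_that("zero tolerance removes sub-threshold effects from both sign sets", {
  g <- gpmap(c(0, 1, 1 - 1e-12, 0, 1, 2, 0, 1, 2))
  # the tiny negative effect is treated as zero under the default tolerance
  expect_true(is_monotone_locus(g, 2))
  expect_equal(degree_of_monotonicity(g)$m, 1)
  # with zero tolerance the same effect counts as negative
  expect_false(is_monotone_locus(g, 2, zero_tol = 0))
})
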