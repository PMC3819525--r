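test_that("connectivity enumeration covers the constrained space exactly", {
  e <- enumerate_connectivity()
  expect_identical(nrow(e), 6859L)
  expect_identical(anyDuplicated(apply(e, 1, paste, collapse = ",")), 0L)
  # each row of A has at most 2 regulators; 19 admissible row patterns
  for (k in 1:3) {
    rows <- e[, paste0("A", k, 1:3)]
    expect_true(all(rowSums(rows != 0) <= 2))
    expect_identical(nrow(unique(rows)), 19L)
  }
  expect_true(any(rowSums(e != 0) == 0))  # zero matrix included
})

test_that("downstream filter keeps 3724 weakly connected matrices", {
  f <- filter_downstream(enumerate_connectivity())
  expect_identical(nrow(f), 3724L)
  # a matrix with only A31 non-zero fails every clause
  only_a31 <- rep(0L, 9); only_a31[7] <- 1L
  expect_identical(nrow(filter_downstream(matrix(only_a31, nrow = 1,
    dimnames = list(NULL, colnames(f))))), 0L)
  # weak connectivity is implied by the filter
  connected <- apply(f, 1, function(flat) {
    A <- matrix(flat, 3, 3, byrow = TRUE)
    und <- (A != 0) | t(A != 0)
    seen <- c(TRUE, FALSE, FALSE)
    for (it in 1:3) seen <- seen | (und %*% seen > 0)
    all(seen)
  })
  expect_true(all(connected))
})

test_that("symmetry reduction leaves 1881 representatives (38 self-symmetric)", {
  f <- filter_downstream(enumerate_connectivity())
  r <- reduce_symmetry(f)
  expect_identical(nrow(r), 1881L)
  swap <- function(flat) flat[c(5, 4, 6, 2, 1, 3, 8, 7, 9)]
  self_sym <- sum(apply(f, 1, function(x) all(swap(x) == x)))
  expect_identical(self_sym, 38L)
  expect_identical(2L * 1881L - self_sym, 3724L)
  # the swap of any representative stays inside its orbit
  keys <- apply(r, 1, paste, collapse = ",")
  swapped_keys <- apply(r, 1, function(x) paste(swap(x), collapse = ","))
  all_keys <- apply(f, 1, paste, collapse = ",")
  expect_true(all(swapped_keys %in% all_keys))
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("loop products follow the defining index formulas", {
  # positive two-gene feedback between X1 and X2
  A_fb <- matrix(0L, 3, 3); A_fb[1, 2] <- 1L; A_fb[2, 1] <- 1L
  lp <- loop_products(A_fb)
  expect_identical(lp$FL12, 1L)
  expect_true(all(unlist(lp[c("FL1", "FL2", "FL3", "FL13", "FL23",
                              "FL123", "FL213", "FFL32", "FFL31")]) == 0L))
  # incoherent feedforward: X1 -> X3 direct (+), X1 -> X2 -> X3 with net -
  A_ff <- matrix(0L, 3, 3); A_ff[3, 1] <- 1L; A_ff[2, 1] <- 1L; A_ff[3, 2] <- -1L
  expect_identical(loop_products(A_ff)$FFL31, -1L)
  expect_true(classify_motif(A_ff)$has_incoherent_ffl)
  # zero matrix: all products zero
  expect_true(all(unlist(loop_products(matrix(0L, 3, 3))) == 0L))
})

test_that("classification splits the 1881 representatives as tabulated", {
  tab <- motif_table()
  expect_identical(nrow(tab), 1881L)
  counts <- table(tab$class)
  expect_identical(as.integer(counts[["both"]]), 287L)
  expect_identical(as.integer(counts[["incoherent_ffl_only"]]), 48L)
  expect_identical(as.integer(counts[["positive_fb_only"]]), 1294L)
  expect_identical(as.integer(counts[["neither"]]), 252L)
  expect_identical(sum(counts), 1881L)
})

test_that("classification is invariant under the X1/X2 swap", {
  f <- filter_downstream(enumerate_connectivity())
  swapped <- f[, c(5, 4, 6, 2, 1, 3, 8, 7, 9)]
  colnames(swapped) <- colnames(f)
  expect_identical(classify_motif(f)$class, classify_motif(swapped)$class)
})

test_that("flatten/unflatten round-trips regardless of dimnames", {
  set.seed(18)
  for (rep in 1:20) {
    flat <- sample(c(-1L, 0L, 1L), 9, replace = TRUE)
    A <- gpmono:::unflatten_connectivity(flat)  # carries dimnames
    expect_identical(as.integer(gpmono:::flatten_connectivity(A)), flat)
    expect_identical(as.integer(gpmono:::flatten_connectivity(unname(A))),
                     flat)
    expect_identical(as.integer(gpmono:::flatten_connectivity(flat)), flat)
    # parameter sampling preserves the wiring it was given
    prm <- sample_genotype_parameters(A)
    expect_identical(unname(prm$A), unname(A))
  }
})

test_that("a pure cascade carries no loops at all", {
  A <- matrix(0L, 3, 3); A[2, 1] <- 1L; A[3, 2] <- 1L
  cl <- classify_motif(A)
  expect_false(cl$has_incoherent_ffl)
  expect_false(cl$has_positive_fb)
  expect_identical(cl$class, "neither")
})
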