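test_that("hill function has the defining threshold, limits and symmetry", {
  for (p in c(1, 2.5, 10)) {
    expect_equal(hill(30, 30, p), 0.5)
  }
  expect_equal(hill(0, 25, 3), 0)
  expect_equal(hill(0, 25, 3, "repressor"), 1)
  y <- seq(0, 100, by = 7)
  expect_equal(hill(y, 30, 4) + hill(y, 30, 4, "repressor"), rep(1, length(y)))
  expect_error(hill(-1, 30, 2), "requires")
  expect_error(hill(1, 0, 2), "requires")
})

test_that("regulation function composes Hill terms with Boolean AND", {
  A <- matrix(0L, 3, 3)
  expect_equal(regulation_function(A, 1, c(5, 5, 5), rep(NA, 3), rep(NA, 3)), 1)
  A[3, 1] <- 1L; A[3, 2] <- 1L
  theta <- c(10, 20, NA); p <- c(2, 3, NA)
  # two activators exactly at their thresholds: 0.5 * 0.5
  expect_equal(regulation_function(A, 3, c(10, 20, 0), theta, p), 0.25)
  A2 <- matrix(0L, 3, 3); A2[1, 2] <- -1L
  expect_lt(regulation_function(A2, 1, c(0, 1e6, 0), c(NA, 30, NA),
                                c(NA, 4, NA)), 1e-10)
  A3 <- matrix(1L, 3, 3)
  expect_error(regulation_function(A3, 1, c(1, 1, 1), rep(30, 3), rep(2, 3)),
               "at most 2")
})

test_that("the ODE right-hand side has the expected structure", {
  A <- matrix(0L, 3, 3)
  set.seed(2)
  prm <- sample_genotype_parameters(A)
  gp <- genotype_parameters(prm, c(0, 1, 2))
  # unregulated gene: fixed point at x = alpha / gamma per allele
  xstar <- as.numeric(t(gp$alpha)) / gp$gamma
  expect_equal(grn_rhs(xstar, gp), rep(0, 6))
  # zero state: derivative equals the production rates
  expect_equal(grn_rhs(rep(0, 6), gp), as.numeric(t(gp$alpha)))
  # fast path agrees with the reference on random states
  Ar <- matrix(c(1L, 0L, -1L, 1L, 0L, 0L, -1L, 1L, 0L), 3, 3, byrow = TRUE)
  prm2 <- sample_genotype_parameters(Ar, pleiotropy = TRUE)
  gp2 <- genotype_parameters(prm2, c(1, 2, 0))
  pc2 <- gpmono:::compile_genotype(gp2)
  for (i in 1:10) {
    st <- runif(6, 0, 50)
    expect_equal(grn_rhs(st, gp2), gpmono:::rhs_fast(st, pc2))
  }
})

test_that("steady state matches the closed form for an unregulated gene", {
  A <- matrix(0L, 3, 3)
  set.seed(3)
  prm <- sample_genotype_parameters(A)
  prm$alpha[, 1] <- 150; prm$alpha[, 2] <- 150
  ss <- steady_state(genotype_parameters(prm, c(0, 0, 0)))
  expect_true(ss$converged)
  expect_equal(ss$y, rep((150 + 150) / 10, 3), tolerance = 1e-6)
  # heterozygote mixes the two allelic production rates
  prm$alpha[3, ] <- c(120, 180)
  ss12 <- steady_state(genotype_parameters(prm, c(0, 0, 1)))
  expect_equal(ss12$phenotype, (120 + 180) / 10, tolerance = 1e-6)
})

test_that("an activator cascade converges and an oscillator is flagged", {
  A <- matrix(0L, 3, 3); A[2, 1] <- 1L; A[3, 2] <- 1L
  set.seed(4)
  prm <- sample_genotype_parameters(A)
  ss <- steady_state(genotype_parameters(prm, c(0, 0, 0)))
  expect_true(ss$converged)
  expect_true(all(ss$state >= 0) && is.finite(ss$phenotype))
  expect_lt(max(abs(grn_rhs(ss$state, genotype_parameters(prm, c(0, 0, 0))))),
            1e-8)
  # steep three-gene negative loop: sustained oscillation, no stable point
  Ao <- matrix(0L, 3, 3); Ao[1, 3] <- -1L; Ao[2, 1] <- -1L; Ao[3, 2] <- -1L
  prmo <- sample_genotype_parameters(Ao)
  prmo$p[!is.na(prmo$p)] <- 10
  prmo$theta[!is.na(prmo$theta)] <- 15
  prmo$alpha[, ] <- 200
  sso <- steady_state(genotype_parameters(prmo, c(0, 0, 0)))
  expect_false(sso$converged)
  expect_identical(sso$reason, "non_convergence")
})

test_that("parameter sampling respects ranges and the pleiotropy switch", {
  A <- matrix(c(0L, 1L, -1L, 1L, 0L, 0L, 1L, 1L, 0L), 3, 3, byrow = TRUE)
  set.seed(6)
  for (rep in 1:10) {
    prm <- sample_genotype_parameters(A, pleiotropy = FALSE)
    expect_true(all(prm$alpha >= 100 & prm$alpha <= 200))
    th <- prm$theta[!is.na(prm$theta)]
    pp <- prm$p[!is.na(prm$p)]
    expect_true(all(th >= 20 & th <= 40))
    expect_true(all(pp >= 1 & pp <= 10))
    # both allelic variants share regulation parameters without pleiotropy
    expect_identical(prm$theta[, , 1], prm$theta[, , 2])
    expect_identical(prm$p[, , 1], prm$p[, , 2])
    expect_identical(prm$gamma, 10)
  }
  prm_p <- sample_genotype_parameters(A, pleiotropy = TRUE)
  expect_false(identical(prm_p$theta[, , 1], prm_p$theta[, , 2]))
  set.seed(8); a <- sample_genotype_parameters(A, TRUE)
  set.seed(8); b <- sample_genotype_parameters(A, TRUE)
  expect_identical(a, b)
  # NA pattern matches the regulatory edges
  expect_identical(is.na(prm_p$theta[, , 1]), t(A == 0L))
})

test_that("homozygote phenotypes are exchangeable under allele relabelling", {
  A <- matrix(0L, 3, 3); A[2, 1] <- 1L; A[3, 2] <- -1L
  set.seed(9)
  prm <- sample_genotype_parameters(A, pleiotropy = TRUE)
  swapped <- prm
  swapped$alpha <- prm$alpha[, 2:1]
  swapped$theta <- prm$theta[, , 2:1]
  swapped$p <- prm$p[, , 2:1]
  for (counts in list(c(0, 0, 0), c(2, 0, 2), c(1, 1, 1))) {
    ph <- steady_state(genotype_parameters(prm, counts))$phenotype
    ph_sw <- steady_state(genotype_parameters(swapped, 2 - counts))$phenotype
    expect_equal(ph, ph_sw, tolerance = 1e-9)
  }
})

test_that("simulate_gpmap assembles 27 genotypes and applies discard rules", {
  # no genetic variation: identical allelic variants give a flat map
  A <- matrix(0L, 3, 3)
  set.seed(10)
  prm <- sample_genotype_parameters(A)
  prm$alpha[, 2] <- prm$alpha[, 1]
  sim <- simulate_gpmap(prm)
  expect_false(sim$ok)
  expect_identical(sim$reason, "flat")
  # variation only at locus 3, no regulation: closed-form additive map
  prm$alpha[3, ] <- c(110, 190)
  sim3 <- simulate_gpmap(prm)
  expect_true(sim3$ok)
  cm <- counts_matrix(3)
  alpha_sum <- c(2 * 110, 110 + 190, 2 * 190)[cm[, 3] + 1]
  expect_equal(sim3$gpmap$values, alpha_sum / 10, tolerance = 1e-8)
  expect_equal(degree_of_monotonicity(sim3$gpmap)$m, 1)
})

test_that("pleiotropy raises the frequency of order-breaking maps", {
  tab <- motif_table()
  both <- tab[tab$class == "both", ]
  set.seed(2)
  sel <- both[sort(sample(nrow(both), 8)), ]
  ob_frac <- function(pleio) {
    s <- monte_carlo_study(sel, grn_config(n_reps = 12, seed = 5,
                                           pleiotropy = pleio))$summary
    sum(s$ob1 + s$ob2 + s$ob3) / sum(s$usable)
  }
  expect_gt(ob_frac(TRUE), ob_frac(FALSE))
})

test_that("the Monte Carlo study is reproducible and accounts for all replicates", {
  tab <- motif_table()
  sel <- tab[tab$class == "neither", ][c(1, 5), ]
  cfg <- grn_config(n_reps = 3, seed = 12)
  mc1 <- monte_carlo_study(sel, cfg)
  mc2 <- monte_carlo_study(sel, cfg)
  expect_identical(mc1$summary, mc2$summary)
  s <- mc1$summary
  expect_true(all(s$usable + s$discarded_nonconvergence + s$discarded_flat ==
                  s$n_reps))
  expect_true(all(s$ob0 + s$ob1 + s$ob2 + s$ob3 == s$usable))
  # subsets reproduce: running one motif alone gives that motif's row
  mc_sub <- monte_carlo_study(sel[1, ], cfg)
  expect_identical(mc_sub$summary, mc1$summary[1, ])
})
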