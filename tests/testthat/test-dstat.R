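# Site terms, pattern terms, modes, blocks, jackknife.

test_that("site terms match the defining polynomials at anchor points", {
  t1 <- site_terms(1, 0, 1, 0)                    # pure BABA
  expect_equal(t1$X, 1); expect_equal(t1$Y, 1)
  expect_equal(t1$pBABA, 1); expect_equal(t1$pABBA, 0)
  t2 <- site_terms(0.37, 0.37, 0.9, 0.1)          # H1 = H2 kills X
  expect_equal(t2$X, 0)
  t3 <- site_terms(0.5, 0.5, 0.5, 0.5)
  expect_equal(t3$X, 0); expect_equal(t3$Y, 0.25)
})

test_that("X = pBABA - pABBA, Y = pABBA + pBABA, |D| <= 1, relabeling", {
  set.seed(42)
  q <- matrix(runif(4e4), ncol = 4)
  st <- site_terms(q[, 1], q[, 2], q[, 3], q[, 4])
  expect_lt(max(abs(st$X - (st$pBABA - st$pABBA))), 1e-12)
  expect_lt(max(abs(st$Y - (st$pABBA + st$pBABA))), 1e-12)
  expect_true(all(abs(st$X) <= st$Y + 1e-12))
  flip <- site_terms(1 - q[, 1], 1 - q[, 2], 1 - q[, 3], 1 - q[, 4])
  expect_lt(max(abs(flip$X - st$X)), 1e-12)
  expect_lt(max(abs(flip$Y - st$Y)), 1e-12)
})

test_that("pattern terms agree with brute-force enumeration", {
  dA <- c(1, 0, 0, 0); dC <- c(0, 1, 0, 0)
  pure <- pattern_terms(dA, dC, dC, dA)           # pure ABBA
  expect_equal(pure$pABBA, 1); expect_equal(pure$X, -1)
  unif <- rep(0.25, 4)
  u <- pattern_terms(unif, unif, unif, unif)
  o <- oracle_pattern_masses(unif, unif, unif, unif)
  expect_equal(u$pABBA, o$pABBA)                  # 12/256 by enumeration
  expect_equal(u$pABBA, 12 / 256)
  expect_equal(u$X, 0)
  set.seed(7)
  for (i in 1:5) {
    f <- list(rsimplex(), rsimplex(), rsimplex(), rsimplex())
    got <- pattern_terms(f[[1]], f[[2]], f[[3]], f[[4]])
    ora <- oracle_pattern_masses(f[[1]], f[[2]], f[[3]], f[[4]])
    expect_equal(got$pABBA, ora$pABBA, tolerance = 1e-12)
    expect_equal(got$pBABA, ora$pBABA, tolerance = 1e-12)
    gt <- pattern_terms(f[[1]], f[[2]], f[[3]], f[[4]], drop_transitions = TRUE)
    ot <- oracle_pattern_masses(f[[1]], f[[2]], f[[3]], f[[4]],
                                drop_transitions = TRUE)
    expect_equal(gt$pABBA, ot$pABBA, tolerance = 1e-12)
    expect_equal(gt$pBABA, ot$pBABA, tolerance = 1e-12)
  }
  expect_error(pattern_terms(c(1, 1, 0, 0), dA, dA, dA), "simplex")
})

test_that("di-allelic pattern input reproduces the scalar site terms", {
  set.seed(8)
  q <- matrix(runif(400), ncol = 4)
  f <- lapply(1:4, function(j) cbind(q[, j], 1 - q[, j], 0, 0))
  pt <- pattern_terms(f[[1]], f[[2]], f[[3]], f[[4]])
  st <- site_terms(q[, 1], q[, 2], q[, 3], q[, 4])
  expect_equal(pt$X, st$X, tolerance = 1e-12)
  expect_equal(pt$Y, st$Y, tolerance = 1e-12)
})

test_that("one-base sampling follows the pooled count proportions", {
  expect_equal(sample_one_base(c(5, 0, 0, 0)), 1L)        # degenerate
  set.seed(3)
  m <- matrix(rep(c(1, 1, 0, 0), each = 1e5), ncol = 4)
  b <- sample_one_base(m)
  pA <- mean(b == 1L)
  expect_lt(abs(pA - 0.5), 3 * sqrt(0.25 / 1e5))          # binomial oracle
  set.seed(99); b1 <- sample_one_base(m)
  set.seed(99); b2 <- sample_one_base(m)
  expect_identical(b1, b2)                                # determinism
  expect_error(sample_one_base(c(0, 0, 0, 0)), "zero")
})

test_that("genotype frequencies are dosage ratios", {
  expect_equal(genotype_freq(c(2, 2)), 1)
  expect_equal(genotype_freq(c(0, 1, 1)), 2 / 6)
  expect_equal(genotype_freq(1), 0.5)
  expect_true(is.na(genotype_freq(c(NA, NA))))
  expect_equal(genotype_freq(c(1, NA)), 0.5)              # missing skipped
})

test_that("transition filter removes exactly the {A,G} and {C,T} pairs", {
  major <- c(1L, 1L, 2L, 3L, 2L, 4L)
  minor <- c(3L, 2L, 4L, 1L, 3L, 2L)
  expect_equal(remove_transitions(major, minor),
               c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("block aggregation is additive and respects boundaries", {
  terms <- list(X = c(1, -1, 0.5), Y = c(1, 1, 0.5))
  b <- aggregate_blocks(terms, rep("c", 3), c(10, 20, 5e6 + 1), 5e6)
  expect_equal(nrow(b), 2)
  expect_equal(b$X, c(0, 0.5))                    # +1 and -1 cancel in block 1
  expect_equal(b$m, c(2L, 1L))
})

test_that("weighted jackknife reduces to the textbook delete-1 formula", {
  set.seed(21)
  X <- rnorm(15, 0.1, 0.3)
  Y <- rep(2.5, 15)                               # equal weights
  res <- jackknife_D(data.frame(X = X, Y = Y, m = 1))
  ora <- oracle_unweighted_jackknife(X, Y)
  expect_equal(res$D, ora$D, tolerance = 1e-12)
  expect_equal(res$SE, ora$SE, tolerance = 1e-10)
  expect_equal(res$Z, res$D / res$SE)
  expect_equal(res$p, 2 * pnorm(-abs(res$Z)))
  # identical blocks: SE = 0, Z undefined signal
  same <- jackknife_D(data.frame(X = rep(0.2, 5), Y = rep(1, 5), m = 1))
  expect_equal(same$SE, 0)
  expect_true(is.na(same$Z))
  # degenerate denominators
  expect_error(jackknife_D(data.frame(X = 1, Y = 0, m = 1)), "denominator|mass")
  one <- jackknife_D(data.frame(X = 1, Y = 2, m = 1))
  expect_true(is.na(one$SE))
  # sign convention flips D but not its magnitude
  fl <- jackknife_D(data.frame(X = X, Y = Y, m = 1),
                    sign_convention = "abba-baba")
  expect_equal(fl$D, -res$D)
})

test_that("compute_D pipeline: H0 genotype identity and mode agreement", {
  # genotype mode with H1 == H2 everywhere gives D = 0 exactly
  set.seed(5)
  ns <- 400
  a <- array(1L, c(ns, 4, 4)) * 0L
  a[, , 1] <- 1L                                  # one A read everywhere
  x <- toy_site_table(a, pos = seq_len(ns), ids = paste0("i", 1:4))
  cfg <- pop_config("i1", "i2", "i3", "i4", block_size = 50)
  g1 <- matrix(rbinom(ns, 2, 0.5), 1)
  g3 <- matrix(rbinom(ns, 2, 0.3), 1)
  g4 <- matrix(rbinom(ns, 2, 0.7), 1)
  res <- compute_D(x, cfg, mode = "genotype",
                   genotypes = list(H1 = g1, H2 = g1, H3 = g3, H4 = g4))
  expect_equal(res$D, 0)
  # with one individual per population and exactly one read per site the
  # extended estimator equals the sampled-base estimator dataset by dataset
  # di-allelic world ({A,C} only) so no reads are lost to the collapse
  set.seed(6)
  b <- array(0L, c(ns, 4, 4))
  drawn <- matrix(sample.int(2, ns * 4, replace = TRUE), ns, 4)
  for (j in 1:4) b[cbind(seq_len(ns), j, drawn[, j])] <- 1L
  xb <- toy_site_table(b, ids = paste0("i", 1:4))
  cfgb <- pop_config("i1", "i2", "i3", "i4", block_size = 50)
  r_ext <- compute_D(xb, cfgb, mode = "extended")
  set.seed(1)
  r_one <- compute_D(xb, cfgb, mode = "one_base")
  expect_equal(r_ext$D, r_one$D, tolerance = 1e-12)
  expect_equal(r_ext$SE, r_one$SE, tolerance = 1e-12)
})

test_that("pattern_blocks + D_from_pattern_blocks equals compute_D", {
  sim <- simulate_scenario(scenario_preset("fig2A",
    list(n_blocks = 5L, sites_per_block = 400L)), seed = 30)
  pb <- pattern_blocks(sim)
  r1 <- D_from_pattern_blocks(pb)
  r2 <- compute_D(sim, mode = "extended", error_matrices = list())
  expect_equal(r1$D, r2$D, tolerance = 1e-12)
  expect_equal(r1$SE, r2$SE, tolerance = 1e-12)
})
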