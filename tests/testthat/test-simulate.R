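# Drift simulator, read sampling, presets.

test_that("presets carry the stated scenario parameters", {
  a <- scenario_preset("fig2A")
  expect_equal(a$Ne, 1e4)
  expect_equal(unname(a$n_dip), rep(5L, 4))
  expect_equal(c(a$t12, a$t123, a$t1234), c(0.5, 0.75, 1.0))
  b <- scenario_preset("fig2B")
  expect_equal(b$error_matrices$H1[1, 3], 0.005)
  expect_equal(b$error_matrices$H3[1, 3], 0.005)
  expect_null(b$error_matrices$H2)
  cc <- scenario_preset("fig2C")
  expect_equal(cc$alpha, 0.1)
  expect_equal(cc$admixed, "H1")
  expect_equal(unname(cc$n_dip), rep(5L, 5))
  # overrides replace only the named fields
  ov <- scenario_preset("fig2A", list(n_blocks = 20L))
  expect_equal(ov$n_blocks, 20L)
  expect_equal(ov$sites_per_block, scenario_preset("fig2A")$sites_per_block)
  expect_error(scenario_preset("fig9"), "preset")
})

test_that("the ms-style migration grid converts to the printed fractions", {
  # rescaled rate 280 corresponds to a migrant fraction of 0.7% per
  # generation; 8 corresponds to 0.02%
  expect_equal(migration_units(280, Ne = 1e4)$per_generation, 0.007)
  expect_equal(migration_units(8, Ne = 1e4)$per_generation, 2e-4)
  expect_equal(migration_units(0)$per_generation, 0)
  expect_equal(migration_units(0)$pulse, 0)
  # the pulse equivalent integrates the per-generation rate over the
  # 40-generation window
  u <- migration_units(280, Ne = 1e4, window_4Ne = 0.001)
  expect_equal(u$pulse, 1 - (1 - 0.007)^40)
})

test_that("drift preserves the mean and realises the expected F_ST", {
  # t = 0 branches: child equals parent (tested through a preset with
  # migration at the split time so no drift segment has zero length)
  set.seed(61)
  sc <- scenario_preset("fig2A", list(t12 = 0.4, migration_time = 0.4))
  f <- simulate_freqs(sc, 3000)
  expect_true(all(f >= 0 & f <= 1))
  # Hudson-style FST between H1 and H2 (split t12 = 0.4 x 4Ne = 16000
  # generations) should approach 1 - exp(-t/(2Ne)) per branch
  set.seed(62)
  sub <- scenario_preset("fig2A", list(segregating_only = FALSE))
  f2 <- simulate_freqs(sub, 5e4)
  num <- mean((f2[, "H1"] - f2[, "H2"])^2)
  den <- mean(f2[, "H1"] * (1 - f2[, "H2"]) + f2[, "H2"] * (1 - f2[, "H1"]))
  fst <- num / den
  expected <- 1 - exp(-0.5 * 4 * 1e4 / (2 * 1e4))
  expect_lt(abs(fst - expected) / expected, 0.15)
  # pulse machinery with rate zero leaves the frequency law unchanged:
  # same RNG seed, same draws
  set.seed(63); a <- simulate_freqs(scenario_preset("fig2A"), 2000)
  set.seed(63); b <- simulate_freqs(scenario_preset("fig2A",
                                      list(migration_ms = 0)), 2000)
  expect_identical(a, b)
})

test_that("genotype sampling is binomial and mean-preserving", {
  set.seed(71)
  g <- simulate_genotypes(rep(0.5, 1e5), 1)
  expect_true(all(g %in% 0:2))
  expect_lt(abs(mean(g) - 1), 3 * sqrt(0.5 / 1e5))
  expect_true(all(simulate_genotypes(rep(1, 100), 2) == 2L))
  set.seed(5); g1 <- simulate_genotypes(runif(100), 3)
  set.seed(5); g2 <- simulate_genotypes(runif(100), 3)
  expect_identical(g1, g2)
})

test_that("read simulation: Poisson depth, dosage sampling, error channel", {
  set.seed(81)
  ns <- 2e4
  g2 <- matrix(2L, 1, ns)
  counts <- simulate_reads(g2, lambda = 5)
  n <- rowSums(counts[, 1, ])
  expect_lt(abs(mean(n) - 5), 3 * sqrt(5 / ns))          # Poisson mean
  expect_true(all(counts[, 1, 2:4] == 0))                # all reads allele A
  # error channel at the stated A->G rate
  e <- type_error_matrix(0.005, "A", "G")
  ce <- simulate_reads(g2, lambda = 5, e = e)
  gfrac <- sum(ce[, 1, 3]) / sum(ce[, 1, ])
  expect_lt(abs(gfrac - 0.005), 3 * sqrt(0.005 / sum(ce[, 1, ])))
  # depth 0.2: zero-coverage fraction matches the Poisson mass at zero
  cl <- simulate_reads(g2, lambda = 0.2)
  p0 <- mean(rowSums(cl[, 1, ]) == 0)
  expect_lt(abs(p0 - exp(-0.2)), 3 * sqrt(exp(-0.2) * (1 - exp(-0.2)) / ns))
  # heterozygotes give a fair read coin
  gh <- matrix(1L, 1, ns)
  ch <- simulate_reads(gh, lambda = 4)
  afrac <- sum(ch[, 1, 1]) / sum(ch[, 1, ])
  expect_lt(abs(afrac - 0.5), 3 * sqrt(0.25 / sum(ch[, 1, ])))
})

test_that("full scenario simulation is reproducible and consistent", {
  sc <- scenario_preset("fig2A", list(n_blocks = 3L, sites_per_block = 300L))
  s1 <- simulate_scenario(sc, seed = 9)
  s2 <- simulate_scenario(sc, seed = 9)
  expect_identical(s1$site_table$counts, s2$site_table$counts)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_equal(n_sites(s1$site_table), 900)
  # segregating retention: no site fixed for the same allele everywhere
  fr <- s1$truth$freqs
  expect_true(all(rowSums(fr > 0) > 0 & rowSums(fr < 1) > 0))
  # frequency estimates converge to the truth at high depth
  deep <- simulate_scenario(scenario_preset("fig2A",
    list(n_blocks = 2L, sites_per_block = 500L, depth = 60)), seed = 10)
  pf <- population_freq(lapply(1:5, function(i)
    deep$site_table$counts[1, i, ]), 1)
  a1 <- deep$truth$alleles$base1[1]
  truth <- deep$truth$freqs[1, "H1"]
  expect_lt(abs(pf$f_hat[[a1]] - truth), 0.15)
})

test_that("the fig2C world carries the admixture pulse", {
  sc0 <- scenario_preset("fig2C", list(alpha = 0,
    n_blocks = 4L, sites_per_block = 500L))
  sc1 <- scenario_preset("fig2C", list(n_blocks = 4L, sites_per_block = 500L))
  set.seed(90); f0 <- simulate_freqs(sc0, 5e3)
  set.seed(90); f1 <- simulate_freqs(sc1, 5e3)
  # with the pulse, H1 correlates more strongly with H5
  c0 <- cor(f0[, "H1"], f0[, "H5"])
  c1 <- cor(f1[, "H1"], f1[, "H5"])
  expect_gt(c1, c0)
})

test_that("sparse invariant bookkeeping is consistent with Poisson thinning", {
  sc <- scenario_preset("fig2B", list(
    n_dip = c(H1 = 1L, H2 = 1L, H3 = 1L, H4 = 1L),
    n_blocks = 4L, sites_per_block = 50000L, theta_per_block = 10))
  sim <- simulate_scenario(sc, seed = 13)
  L <- sc$sites_per_block
  expect_equal(dim(sim$pure_sites), c(4L, 4L))
  # pure + explicit never exceed the positions simulated
  expect_lte(sum(sim$pure_sites) + n_sites(sim$site_table), 4L * L)
  # the hit-site fraction of invariant-A positions matches the thinned
  # Poisson rate 1 - exp(-sum_i lambda * e_i(A, not A))
  lam_err <- 2 * sc$depth * 0.005          # two error individuals
  d <- depth_matrix(sim$site_table)
  # A-invariant hit sites are those with G reads and no C/T variation;
  # approximate count: explicit sites minus polymorphic ones
  n_poly_exp <- 4L * L * sum(1 / seq_len(2 * 4 - 1)) * 10 / L
  n_hit <- n_sites(sim$site_table) - n_poly_exp
  expected_hits <- 4L * L / 4 * (1 - exp(-lam_err))
  expect_lt(abs(n_hit - expected_hits) / expected_hits, 0.15)
  # pure-site count matches coverage x no-hit probability per base
  p_cov <- (1 - exp(-sc$depth))^2 * (1 - exp(-sc$depth * 0.995)) ^ 2
  expA <- L / 4 * exp(-lam_err) * p_cov
  expect_lt(abs(mean(sim$pure_sites[, 1]) - expA) / expA, 0.1)
  # pattern blocks fold the pure masses into the monomorphic patterns
  pb <- pattern_blocks(sim)
  mono_cols <- c(1L, 86L, 171L, 256L)
  expect_true(all(pb$P[, mono_cols] >= sim$pure_sites))
  expect_true(all(pb$m >= rowSums(sim$pure_sites)))
  # without any error matrix the explicit sites are the polymorphic ones
  sc0 <- scenario_preset("fig2B", list(
    n_dip = c(H1 = 1L, H2 = 1L, H3 = 1L, H4 = 1L),
    n_blocks = 4L, sites_per_block = 50000L, theta_per_block = 10,
    error_matrices = NULL))
  sim0 <- simulate_scenario(sc0, seed = 13)
  expect_lt(n_sites(sim0$site_table), 300)
  r0 <- D_from_pattern_blocks(pattern_blocks(sim0))
  expect_true(is.finite(r0$D))
})
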