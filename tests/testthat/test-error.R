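# Error-matrix estimation and pattern-space correction.

test_that("error_matrix validates stochasticity", {
  expect_s3_class(error_matrix(diag(4)), "error_matrix")
  expect_error(error_matrix(matrix(0.3, 4, 4)), "sum to 1")
  bad <- diag(4); bad[1, 1] <- 1.5; bad[1, 2] <- -0.5
  expect_error(error_matrix(bad), "\\[0,1\\]")
})

test_that("trio estimation recovers known error structures", {
  # identical T and R counts: no excess error, e = identity
  cnt <- matrix(c(900, 5, 3, 2,
                  4, 950, 1, 5,
                  2, 3, 870, 5,
                  1, 2, 6, 990), 4, 4, byrow = TRUE)
  e <- estimate_error_matrix(cnt, cnt)
  expect_equal(unclass(e), diag(4), tolerance = 1e-6, ignore_attr = TRUE)
  # R has zero mismatches (P_R = I): solution is T's row-normalised counts
  cT <- matrix(0, 4, 4)
  diag(cT) <- 990000
  cT[row(cT) != col(cT)] <- 10000 / 3
  cR <- diag(c(1e6, 1e6, 1e6, 1e6))
  e2 <- estimate_error_matrix(cT, cR)
  expect_equal(unclass(e2), cT / rowSums(cT), tolerance = 1e-6,
               ignore_attr = TRUE)
  # forward simulation at the stated A->G rate
  set.seed(202)
  etrue <- type_error_matrix(0.005, "A", "G")
  trio <- simulate_error_trio(etrue, n_sites = 2e5, depth = 5)
  ehat <- estimate_error_matrix(trio$counts_T_vs_O, trio$counts_R_vs_O)
  n_A <- sum(trio$counts_T_vs_O[1, ])
  mc_se <- sqrt(0.005 * 0.995 / n_A) +
    sqrt(mean(trio$counts_R_vs_O[1, 3] / sum(trio$counts_R_vs_O[1, ])) /
           sum(trio$counts_R_vs_O[1, ]))
  expect_lt(abs(ehat[1, 3] - 0.005), 3 * mc_se)
  expect_equal(rowSums(unclass(ehat)), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("individual frequency correction inverts the read channel", {
  e <- error_matrix(matrix(c(0.97, 0.01, 0.01, 0.01,
                             0.02, 0.94, 0.02, 0.02,
                             0.03, 0.01, 0.95, 0.01,
                             0.01, 0.02, 0.02, 0.95), 4, 4, byrow = TRUE))
  p_true <- c(0.5, 0.2, 0.2, 0.1)
  p_obs <- as.vector(t(unclass(e)) %*% p_true)
  rec <- correct_individual_freqs(p_obs, e)
  expect_equal(as.vector(rec), p_true, tolerance = 1e-12)
  expect_equal(correct_individual_freqs(p_true, error_matrix(diag(4))),
               p_true, ignore_attr = TRUE)
  # strong error can give negative entries; clamp keeps a simplex
  strong <- error_matrix(matrix(c(0.5, 0.5, 0, 0,
                                  0.4, 0.6, 0, 0,
                                  0, 0, 1, 0,
                                  0, 0, 0, 1), 4, 4, byrow = TRUE),
                         tol = 1e-6) |> suppressWarnings()
  out <- correct_individual_freqs(c(0.9, 0.1, 0, 0), strong)
  expect_true(all(out >= 0))
  expect_equal(sum(out), 1, tolerance = 1e-9)
  raw <- correct_individual_freqs(c(0.9, 0.1, 0, 0), strong,
                                  negativity = "strict")
  expect_true(any(raw < 0))
})

test_that("population mean error matrix is the entrywise average", {
  e1 <- type_error_matrix(0.01, "A", "G")
  e2 <- type_error_matrix(0.03, "A", "G")
  m <- mean_population_error(list(e1, e2))
  expect_equal(m[1, 3], 0.02)
  expect_equal(unclass(mean_population_error(list(e1))), unclass(e1),
               ignore_attr = TRUE)
})

test_that("factored group operator matches the dense 256x256 oracle", {
  set.seed(17)
  mk <- function() {
    m <- diag(4) * 0.9 + matrix(runif(16, 0, 0.1), 4, 4)
    m / rowSums(m)
  }
  es <- list(mk(), mk(), mk(), mk())
  ge <- build_group_error_matrix(es[[1]], es[[2]], es[[3]], es[[4]],
                                 dense = TRUE)
  E_oracle <- oracle_dense_E(es[[1]], es[[2]], es[[3]], es[[4]])
  expect_equal(ge$E, E_oracle, tolerance = 1e-12)
  # identity factors give the identity operator
  gid <- build_group_error_matrix(diag(4), diag(4), diag(4), diag(4))
  p <- rsimplex256()
  expect_equal(gid$apply(p), p, tolerance = 1e-12)
  # application and correction agree with dense algebra on random vectors
  expect_equal(ge$apply(p), as.vector(t(E_oracle) %*% p), tolerance = 1e-10)
  expect_equal(ge$correct(p), as.vector(solve(t(E_oracle), p)),
               tolerance = 1e-10)
  # row-stochastic operator conserves total mass
  expect_equal(sum(ge$apply(p)), sum(p), tolerance = 1e-12)
  # Kronecker inverse identity: correcting the applied vector is a no-op
  expect_equal(ge$correct(ge$apply(p)), p, tolerance = 1e-10)
  # E entry for AAAA -> AAAA is the product of the diagonal entries
  expect_equal(ge$E[1, 1], prod(sapply(es, function(m) m[1, 1])))
})

test_that("pattern correction round-trips an error-contaminated distribution", {
  set.seed(23)
  e1 <- type_error_matrix(0.02, "A", "G")
  e3 <- type_error_matrix(0.01, "C", "T")
  elist <- list(e1, diag(4), e3, diag(4))
  ge <- build_group_error_matrix(elist[[1]], elist[[2]], elist[[3]], elist[[4]])
  p_true <- rsimplex256()
  p_err <- ge$apply(p_true)
  rec <- correct_pattern_probs(p_err, elist, negativity = "strict")
  expect_equal(as.vector(rec), p_true, tolerance = 1e-10)
  # identity correction leaves the vector unchanged
  idc <- correct_pattern_probs(p_err, list(diag(4), diag(4), diag(4), diag(4)))
  expect_equal(as.vector(idc), p_err, tolerance = 1e-12)
  # matrix (block-wise) input corrects each row
  PB <- rbind(p_err, 2 * p_err)
  recB <- correct_pattern_probs(PB, elist, negativity = "strict")
  expect_equal(recB[2, ], 2 * p_true, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("negativity policy clamps and renormalises", {
  v <- c(-0.1, 0.6, 0.5)
  cl <- apply_negativity_policy(v)
  expect_equal(sum(cl), sum(v), tolerance = 1e-12)
  expect_true(all(cl >= 0))
  expect_equal(attr(cl, "clamped_mass"), 0.1)
  st <- apply_negativity_policy(v, "strict")
  expect_equal(as.vector(st), v)
})
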