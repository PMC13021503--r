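# Moment-matched bivariate pair data for a given component structure: the
# sample moments equal the implied moments exactly, so the ML solution must
# reproduce the generating matrices up to optimizer tolerance.
matched_biv_pairs <- function(n_mz, n_dz, A, C, E,
                              traits = c("x", "y")) {
  tr <- ace_truth(A, C, E, traits = traits)
  as_twin_pairs(exact_mvn(n_mz, implied_pair_covariance(tr, "MZ")),
                exact_mvn(n_dz, implied_pair_covariance(tr, "DZ")), traits)
}

test_that("Cholesky fit recovers a moment-matched AE structure", {
  set.seed(71)
  A <- matrix(c(1, 0.5, 0.5, 1), 2)
  prs <- matched_biv_pairs(300, 200, A, matrix(0, 2, 2), diag(2))
  fit <- twin_cholesky(prs, "AE")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$A - A)), 1e-3)
  expect_lt(max(abs(fit$E - diag(2))), 1e-3)
  # the loading matrix reproduces A = X X' with X lower triangular
  expect_equal(fit$X[1, 2], 0)
  expect_equal(unname(tcrossprod(fit$X)), unname(fit$A), tolerance = 1e-10)
  cc <- component_correlations(fit)
  expect_equal(cc$r_A[1, 2], 0.5, tolerance = 2e-3)
})

test_that("component correlations standardize the implied matrices", {
  set.seed(72)
  A <- matrix(c(2, 1, 1, 2), 2)          # r_A = 1/sqrt(4) = 0.5
  C <- diag(c(0.5, 0.5))                 # r_C = 0 off the diagonal
  E <- diag(c(0.7, 0.9))
  prs <- matched_biv_pairs(400, 300, A, C, E)
  cc <- component_correlations(twin_cholesky(prs, "ACE"))
  expect_equal(cc$r_A[1, 2], 0.5, tolerance = 5e-3)
  expect_lt(abs(cc$r_C[1, 2]), 0.05)
  for (M in list(cc$r_A, cc$r_C, cc$r_E)) {
    expect_equal(M, t(M))
    expect_equal(unname(diag(M)), c(1, 1))
    expect_true(all(M >= -1 & M <= 1))
  }
})

test_that("implied matrices are order invariant and PSD on every fit", {
  set.seed(73)
  A <- matrix(c(0.7, 0.4, 0.4, 0.6), 2)
  C <- matrix(c(0.1, 0.05, 0.05, 0.15), 2)
  E <- matrix(c(0.2, 0.08, 0.08, 0.25), 2)
  tr <- ace_truth(A, C, E, traits = c("x", "y"))
  coh <- simulate_twins(pair_design(1200, 1200), tr, seed = 74)
  f_xy <- twin_cholesky(twin_pairs(coh, c("x", "y")), "ACE")
  f_yx <- twin_cholesky(twin_pairs(coh, c("y", "x")), "ACE")
  perm <- c(2, 1)
  expect_lt(max(abs(f_xy$A - f_yx$A[perm, perm])), 1e-4)
  expect_lt(max(abs(f_xy$C - f_yx$C[perm, perm])), 1e-4)
  expect_lt(max(abs(f_xy$E - f_yx$E[perm, perm])), 1e-4)
  r1 <- component_correlations(f_xy)$r_A[1, 2]
  r2 <- component_correlations(f_yx)$r_A[1, 2]
  expect_equal(r1, r2, tolerance = 1e-4)
  for (M in list(f_xy$A, f_xy$C, f_xy$E)) {
    expect_gte(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("the k = 1 Cholesky fit reproduces the univariate estimates", {
  tr <- univariate_truth(0.6, 0.2, 0.2)
  coh <- simulate_twins(pair_design(600, 400), tr, seed = 75)
  prs <- twin_pairs(coh, "trait")
  uni <- twin_ace(prs, "ACE")
  chl <- twin_cholesky(prs, "ACE")
  P <- (chl$A + chl$C + chl$E)[1, 1]
  comps <- c(chl$A[1, 1], chl$C[1, 1], chl$E[1, 1]) / P
  expect_equal(unname(uni$components), comps, tolerance = 1e-4)
  expect_equal(uni$minus2LL, chl$minus2LL, tolerance = 1e-6)
})

test_that("pairwise matrix pipeline recovers a planted correlation block", {
  # four clustered traits (pairwise r_A = 0.9) plus one unrelated trait
  set.seed(76)
  k <- 5
  Ra <- diag(k)
  Ra[1:4, 1:4] <- 0.9; diag(Ra) <- 1
  A <- 0.7 * Ra
  C <- 0.1 * Ra   # proportional, so the AE fit absorbs C without distorting r_A
  E <- diag(0.2, k)
  traits <- paste0("t", 1:k)
  tr <- ace_truth(A, C, E, traits = traits)
  coh <- simulate_twins(pair_design(2000, 2000), tr, seed = 77)
  gc <- genetic_correlation_matrix(coh, traits, models = c("AE", "ACE"))
  expect_identical(nrow(gc$failures), 0L)
  off_block <- gc$r_A_AE[1:4, 5]
  in_block <- gc$r_A_AE[1:4, 1:4][upper.tri(diag(4))]
  expect_true(all(abs(in_block - 0.9) < 0.1))
  expect_true(all(abs(off_block) < 0.1))
  # ACE confirmation moves the genetic correlations only modestly
  d <- gc$delta_r_A[upper.tri(gc$delta_r_A)]
  expect_lt(mean(abs(d)), 0.05)
})

test_that("cross-wave correlations handle the degenerate stable trait", {
  tr <- univariate_truth(0.6, 0.2, 0.2, trait = "h")
  coh <- simulate_twins(pair_design(50, 30, waves = c("w1", "w2")), tr,
                        seed = 78)
  # make the trait identical at both waves: perfect stability
  w1 <- coh$wave == "w1"
  key <- paste(coh$family_id, coh$twin_index)
  coh$h[!w1] <- coh$h[w1][match(key[!w1], key[w1])]
  cw <- suppressWarnings(cross_wave_correlations(coh, "h",
                                                 waves = c("w1", "w2")))
  expect_equal(cw$r, 1, tolerance = 1e-10)
  # the bivariate fit cannot proceed on a singular covariance; the
  # phenotypic correlation must still be reported, never fabricated
  expect_true(!is.null(cw$fit_error) || abs(cw$r_A - 1) < 1e-2)
})

test_that("profile interval for a genetic correlation covers the truth", {
  set.seed(79)
  ra <- 0.6
  A <- 0.7 * matrix(c(1, ra, ra, 1), 2)
  C <- diag(0.1, 2)
  E <- diag(0.2, 2)
  prs <- matched_biv_pairs(500, 300, A, C, E)
  fit <- twin_cholesky(prs, "ACE")
  ci <- profile_corr_ci(fit, "A")
  expect_lt(ci["lower"], ra)
  expect_gt(ci["upper"], ra)
  expect_gte(ci["lower"], -1)
  expect_lte(ci["upper"], 1)
})
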