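test_that("row counts follow the design bookkeeping", {
  tr <- univariate_truth(0.6, 0.2, 0.2)
  coh <- simulate_twins(pair_design(10, 0), tr, seed = 1)
  expect_identical(nrow(coh), 20L)
  expect_true(all(table(coh$family_id) == 2))
  expect_setequal(unique(coh$zygosity), "MZ")

  d <- mtfs_design()
  tr2 <- univariate_truth(0.7, 0.2, 0.1, trait = "height")
  coh2 <- simulate_twins(d, tr2, seed = 2)
  expect_identical(sum(coh2$wave == "intake"), 1512L)
  expect_identical(sum(coh2$wave == "followup"),
                   2L * sum(d$waves[[2]]$pair_counts))
  # co-twins share zygosity, sex and age; ages inside the printed ranges
  expect_true(all(tapply(coh2$sex, coh2$family_id,
                         function(x) length(unique(x))) == 1))
  fup_f <- coh2$wave == "followup" & coh2$sex == "female"
  expect_true(all(coh2$age[fup_f] >= 16.6 & coh2$age[fup_f] <= 20.3))
})

test_that("identical seed gives a byte-identical cohort file", {
  tr <- univariate_truth(0.5, 0.3, 0.2, trait = "w", lognormal = TRUE)
  d <- pair_design(30, 20)
  a <- simulate_twins(d, tr, seed = 99)
  b <- simulate_twins(d, tr, seed = 99)
  expect_identical(a, b)
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_cohort(a, fa); write_cohort(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa) + 10),
                   readBin(fb, "raw", file.size(fb) + 10))
  expect_equal(read_cohort(fa)$w, a$w, tolerance = 1e-12)
  # and a different seed gives different data
  expect_false(identical(a$w, simulate_twins(d, tr, seed = 100)$w))
  expect_error(simulate_twins(d, tr), "seed")
})

test_that("simulated co-twin correlation matches the implied value", {
  tr <- univariate_truth(0.6, 0.2, 0.2)
  coh <- simulate_twins(pair_design(10000, 0), tr, seed = 7)
  prs <- twin_pairs(coh, "trait")
  r <- cotwin_correlations(prs)
  expect_equal(r$r[r$zygosity == "MZ"], 0.80, tolerance = 0.0125)
})

test_that("log-normal traits are strictly positive", {
  tr <- univariate_truth(0.5, 0.2, 0.3, trait = "w", mean = 3,
                         lognormal = TRUE)
  coh <- simulate_twins(pair_design(500, 500), tr, seed = 3)
  expect_true(all(coh$w > 0))
})

test_that("empirical pair covariance converges to the implied matrix", {
  A <- matrix(c(0.6, 0.3, 0.3, 0.5), 2)
  C <- matrix(c(0.15, 0.1, 0.1, 0.2), 2)
  E <- diag(c(0.25, 0.3))
  tr <- ace_truth(A, C, E, traits = c("x", "y"))
  coh <- simulate_twins(pair_design(20000, 0), tr, seed = 11)
  prs <- twin_pairs(coh, c("x", "y"))
  emp <- cov(prs$mz) * (nrow(prs$mz) - 1) / nrow(prs$mz)
  imp <- implied_pair_covariance(tr, "MZ")
  expect_lt(norm(emp - imp, "F"), 0.05 * norm(imp, "F"))
})

test_that("MCAR missingness hits the requested rate", {
  tr <- univariate_truth(0.6, 0.2, 0.2)
  coh <- simulate_twins(pair_design(4000, 0), tr, seed = 5, missing = 0.2)
  expect_lt(abs(mean(is.na(coh$trait)) - 0.2), 0.015)
})
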