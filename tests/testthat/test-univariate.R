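make_stratum_table <- function() {
  # 3 complete MZ pairs, 2 complete DZ pairs, 1 MZ pair with a missing
  # co-twin value, all male, one wave
  fam <- c(rep(sprintf("m%02d", 1:4), each = 2), "d01", "d01", "d02", "d02")
  zyg <- c(rep("MZ", 8), rep("DZ", 4))
  y <- c(1.2, 1.1, 0.4, 0.6, -0.3, -0.1, 0.9, NA, 0.2, 0.8, -0.5, 0.1)
  data.frame(family_id = fam, twin_index = rep(1:2, 6), zygosity = zyg,
             sex = "male", wave = "w", age = 12, y = y,
             stringsAsFactors = FALSE)
}

test_that("pair extraction keeps twin order and honours completeness", {
  tab <- make_stratum_table()
  prs <- twin_pairs(tab, "y")
  expect_identical(nrow(prs$mz), 3L)
  expect_identical(nrow(prs$dz), 2L)
  # twin ordering by stored index, never by value
  expect_equal(unname(prs$mz[1, ]), c(1.2, 1.1))
  fiml <- twin_pairs(tab, "y", complete = FALSE)
  expect_identical(nrow(fiml$mz), 4L)
  expect_true(is.na(fiml$mz[4, 2]))
  expect_error(twin_pairs(tab, "y", sex = "female"), "no rows")
})

test_that("saturated fit moment-matches with 10 parameters and nests", {
  set.seed(52)
  prs <- moment_matched_pairs(60, 40, 0.5, 0.3, 0.2)
  sat <- twin_saturated(prs)
  expect_identical(sat$n_params, 10L)
  n <- nrow(prs$mz)
  emp <- cov(prs$mz) * (n - 1) / n
  expect_equal(max(abs(sat$moments$MZ$S - emp)), 0, tolerance = 1e-6)
  ace <- twin_ace(prs, "ACE")
  ae <- twin_ace(prs, "AE")
  expect_lte(sat$minus2LL, ace$minus2LL + 1e-6)
  expect_lte(ace$minus2LL, ae$minus2LL + 1e-6)
})

test_that("ML estimates equal the generating components on moment-matched data", {
  set.seed(53)
  prs <- moment_matched_pairs(500, 400, 0.6, 0.2, 0.2)
  fit <- twin_ace(prs, "ACE")
  expect_true(fit$converged)
  expect_equal(unname(fit$components), c(0.6, 0.2, 0.2), tolerance = 2e-4)
  expect_equal(sum(fit$components), 1, tolerance = 1e-8)
  expect_gt(fit$components["e2"], 0)

  # pure-E structure: no co-twin resemblance
  prs0 <- moment_matched_pairs(500, 400, 0, 0, 1)
  fit0 <- twin_ace(prs0, "ACE")
  expect_equal(unname(fit0$components), c(0, 0, 1), tolerance = 1e-3)
})

test_that("ML agrees with the closed-form moment oracle on balanced data", {
  # moment-balanced groups: the double-entry correlations are then exact and
  # the just-identified ML solution must land on the same components
  set.seed(54)
  for (truth in list(c(0.5, 0.3, 0.2), c(0.35, 0.4, 0.25))) {
    prs <- moment_matched_pairs(400, 400, truth[1], truth[2], truth[3])
    fit <- twin_ace(prs, "ACE")
    oracle <- moment_ace(prs)
    expect_equal(unname(fit$components), unname(oracle), tolerance = 1e-3)
    expect_equal(unname(oracle), truth, tolerance = 1e-8)
  }
})

test_that("standardized components are invariant to affine trait rescaling", {
  set.seed(55)
  tr <- univariate_truth(0.7, 0.1, 0.2)
  prs <- twinmorph:::.simulate_pairs(tr, 400, 300)
  scaled <- as_twin_pairs(prs$mz * 10, prs$dz * 10, "t")
  f1 <- twin_ace(prs, "ACE")
  f2 <- twin_ace(scaled, "ACE")
  expect_equal(f1$components, f2$components, tolerance = 1e-8)
  expect_equal(f2$paths, f1$paths * 10, tolerance = 1e-6)
  expect_equal(f2$mean, f1$mean * 10, tolerance = 1e-6)
})

test_that("full-information likelihood uses incomplete pairs", {
  tr <- univariate_truth(0.6, 0.2, 0.2)
  coh <- simulate_twins(pair_design(4000, 2500), tr, seed = 31,
                        missing = 0.3)
  fiml <- twin_ace(twin_pairs(coh, "trait", complete = FALSE), "ACE")
  expect_true(fiml$converged)
  expect_lt(max(abs(fiml$components - c(0.6, 0.2, 0.2))), 0.08)
  # FIML sees more pairs than the complete-pairs analysis
  comp <- twin_pairs(coh, "trait")
  expect_gt(fiml$n_pairs["MZ"], nrow(comp$mz))
})

test_that("likelihood-ratio tests count parameters correctly", {
  set.seed(56)
  prs <- moment_matched_pairs(80, 60, 0.5, 0.3, 0.2)
  ace <- twin_ace(prs, "ACE")
  ae <- twin_ace(prs, "AE")
  sat <- twin_saturated(prs)
  expect_identical(twin_lrt(ace, sat)$df, 6L)
  expect_identical(twin_lrt(ae, ace)$df, 1L)
  same <- twin_lrt(ace, ace)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_error(twin_lrt(sat, ace), "fewer parameters")
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 37), 0.05 / 37)
  expect_lt(bonferroni_threshold(0.05, 37), 0.00136)  # prints as p < 0.001
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

test_that("double-entry co-twin correlations are symmetric in twin labels", {
  X <- cbind(c(1, 2, 3, 4), c(1.5, 1.9, 3.4, 3.8))
  prs <- as_twin_pairs(X, X[4:1, ], "t")
  r1 <- cotwin_correlations(prs)
  swapped <- as_twin_pairs(X[, 2:1], X[4:1, 2:1], "t")
  r2 <- cotwin_correlations(swapped)
  expect_equal(r1$r, r2$r)
  ident <- as_twin_pairs(cbind(1:4, 1:4), cbind(5:8 / 2, 5:8 / 2), "t")
  expect_equal(cotwin_correlations(ident)$r, c(1, 1))
  flat <- as_twin_pairs(cbind(rep(1, 4), rep(1, 4)), X, "t")
  expect_warning(cotwin_correlations(flat), "zero variance")
})

test_that("profile intervals bracket the estimate and hit the boundary", {
  set.seed(57)
  prs <- moment_matched_pairs(252, 124, 0.62, 0.18, 0.20)
  fit <- twin_ace(prs, "ACE")
  ci <- confint(fit)
  for (cp in rownames(ci)) {
    expect_lte(ci[cp, "lower"], fit$components[cp] + 1e-6)
    expect_gte(ci[cp, "upper"], fit$components[cp] - 1e-6)
  }
  expect_true(all(ci >= 0 & ci <= 1))
  # c2 estimated at the boundary reports a 0.00 lower limit
  prs0 <- moment_matched_pairs(252, 124, 0.7, 0, 0.3)
  fit0 <- suppressWarnings(twin_ace(prs0, "ACE"))
  expect_lt(fit0$components["c2"], 1e-3)
  ci0 <- confint(fit0, "c2")
  expect_identical(unname(ci0["c2", "lower"]), 0)
})

test_that("bootstrap fallback intervals are sane", {
  set.seed(58)
  prs <- moment_matched_pairs(200, 150, 0.6, 0.2, 0.2)
  fit <- twin_ace(prs, "ACE")
  ci <- confint(fit, "a2", method = "boot", nboot = 60, seed = 4)
  expect_lt(ci["a2", "lower"], 0.6)
  expect_gt(ci["a2", "upper"], 0.6)
})
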