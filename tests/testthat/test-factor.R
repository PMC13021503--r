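test_that("identity correlations yield zero loadings", {
  fs <- principal_factor(diag(6), 2)
  expect_true(fs$converged)
  expect_equal(max(abs(fs$loadings)), 0)
  expect_equal(unname(fs$communalities), rep(0, 6))
})

test_that("rank-1 structure recovers the single factor in closed form", {
  lam <- rep(0.8, 6)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  fs <- principal_factor(R, 1, rotation = "none")
  expect_true(fs$converged)
  expect_equal(unname(fs$loadings[, 1]), lam, tolerance = 1e-4)
  expect_equal(unname(fs$communalities), rep(0.64, 6), tolerance = 1e-4)
})

test_that("three-block structure is recovered with varimax simple structure", {
  R <- block_corr(5, 3)
  fs <- principal_factor(R, 3)
  expect_true(fs$converged)
  blocks <- rep(1:3, each = 5)
  assigned <- apply(abs(fs$loadings), 1, which.max)
  # every trait's top loading on its own block's factor
  for (b in 1:3) {
    expect_identical(length(unique(assigned[blocks == b])), 1L)
  }
  expect_identical(length(unique(tapply(assigned, blocks, unique))), 3L)
  # rotation leaves communalities and the reproduced matrix unchanged
  un <- principal_factor(R, 3, rotation = "none")
  expect_equal(fs$communalities, un$communalities, tolerance = 1e-8)
  expect_equal(tcrossprod(fs$loadings), tcrossprod(un$loadings),
               tolerance = 1e-8)
  # varimax criterion does not decrease
  crit <- function(L) sum(apply(L^2, 2, function(x) mean(x^2) - mean(x)^2))
  expect_gte(crit(fs$loadings), crit(un$loadings) - 1e-10)
  # reproduced-correlation distance is monotone over the iterations
  expect_true(all(diff(un$fit_history) <= 1e-10))
})

test_that("perfect simple structure is a varimax fixed point", {
  L0 <- rbind(matrix(c(0.8, 0), 4, 2, byrow = TRUE),
              matrix(c(0, 0.7), 4, 2, byrow = TRUE))
  R <- tcrossprod(L0) + diag(1 - rowSums(L0^2))
  fs <- principal_factor(R, 2)
  # same loadings up to column order/sign (sign fixed positive here)
  got <- fs$loadings[, order(colSums(fs$loadings^2), decreasing = TRUE)]
  expect_equal(abs(got[, 1]), c(rep(0.8, 4), rep(0, 4)), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(abs(got[, 2]), c(rep(0, 4), rep(0.7, 4)), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("Heywood cases are clipped and flagged", {
  R <- matrix(c(1, 0.8, 0.8, 0.8, 1, 0.55, 0.8, 0.55, 1), 3)
  # PSD, but the implied single-factor loading for trait 1 exceeds 1
  # (0.8 * 0.8 / 0.55 > 1)
  fs <- principal_factor(R, 1, rotation = "none")
  expect_true(all(fs$communalities <= 1 + 1e-6))
  expect_true(fs$heywood)
})

test_that("input validation rejects malformed correlation matrices", {
  expect_error(principal_factor(matrix(c(2, 0, 0, 2), 2), 1), "correlation")
  expect_error(principal_factor(matrix(c(1, 2, 2, 1), 2), 1),
               "positive semidefinite")
  expect_error(principal_factor(diag(3), 3), "n_factors")
  bad <- matrix(0.99, 3, 3); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(principal_factor(bad, 1), "positive semidefinite")
})
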