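test_that("BMI formula and scale consistency", {
  expect_equal(compute_bmi(41.3, 149), 18.60, tolerance = 5e-4)
  expect_equal(compute_bmi(65.2, 166), 23.66, tolerance = 5e-4)
  expect_equal(compute_bmi(70, 100), 70)
  expect_equal(compute_bmi(2 * 80, 175), 2 * compute_bmi(80, 175))
  expect_equal(compute_bmi(80, 2 * 175), compute_bmi(80, 175) / 4)
  expect_error(compute_bmi(-1, 170), "positive")
  expect_error(compute_bmi(60, 0), "positive")
})

test_that("log transformation normalizes a log-normal trait", {
  tab <- data.frame(family_id = "f1", twin_index = 1, zygosity = "MZ",
                    sex = "male", wave = "w", age = 12,
                    x = c(1, exp(1)), y = c(2, 3))
  out <- log_transform(tab, "x")
  expect_equal(out$x, c(0, 1))
  expect_equal(out$y, tab$y)  # untouched

  tr <- univariate_truth(0.5, 0.2, 0.3, trait = "w", lognormal = TRUE)
  coh <- simulate_twins(pair_design(5000, 0), tr, seed = 8)
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  expect_gt(skew(coh$w), 0.5)  # raw scale is right-skewed
  lg <- log_transform(coh, "w")
  expect_lt(abs(skew(lg$w)), 0.1)

  tab$x[1] <- -2
  expect_error(log_transform(tab, "x"), "f1")
})

test_that("age residualization removes the age effect within strata", {
  set.seed(42)
  n <- 2000
  tab <- data.frame(
    family_id = rep(sprintf("f%04d", 1:(n / 2)), each = 2),
    twin_index = rep(1:2, n / 2), zygosity = "MZ",
    sex = rep(c("male", "female"), each = n / 2), wave = "w",
    age = runif(n, 11, 13))
  tab$y <- 2.0 * tab$age + rnorm(n, sd = 0.3)
  # recover the stratum slope before checking the residuals
  males <- tab$sex == "male"
  slope <- coef(lm(y ~ age, tab[males, ]))["age"]
  expect_equal(unname(slope), 2.0, tolerance = 0.05)
  out <- residualize_age(tab, "y")
  for (sx in c("male", "female")) {
    rows <- tab$sex == sx
    expect_lt(abs(mean(out$y[rows])), 1e-10)
    expect_lt(abs(cor(out$y[rows], tab$age[rows])), 1e-12)
  }
  # idempotence
  out2 <- residualize_age(out, "y")
  expect_equal(out2$y, out$y, tolerance = 1e-10)
  # constant trait -> all residuals zero
  tab$z <- 5
  expect_equal(residualize_age(tab, "z")$z, rep(0, n))
  # trait exactly uncorrelated with age -> centering only
  tab$u <- NA_real_
  for (sx in c("male", "female")) {
    rows <- tab$sex == sx
    raw <- rnorm(sum(rows))
    tab$u[rows] <- 10 + residuals(lm(raw ~ tab$age[rows]))
  }
  resu <- residualize_age(tab, "u")$u
  expect_equal(resu[tab$sex == "male"],
               unname(tab$u[tab$sex == "male"] - mean(tab$u[tab$sex == "male"])),
               tolerance = 1e-10)
  expect_error(residualize_age(tab[1:2, ], "y"), "fewer than 3")
})

test_that("log-then-residualize equals residualize of the logged trait", {
  tr <- univariate_truth(0.5, 0.2, 0.3, trait = "w", mean = 3,
                         age_slope = 0.05, lognormal = TRUE)
  coh <- simulate_twins(pair_design(300, 200), tr, seed = 12)
  a <- residualize_age(log_transform(coh, "w"), "w")
  b <- log_transform(coh, "w")
  b <- residualize_age(b, "w")
  expect_equal(a$w, b$w, tolerance = 1e-12)
})

test_that("descriptive statistics summarize each stratum cell", {
  tab <- data.frame(family_id = c("a", "a", "b"), twin_index = c(1, 2, 1),
                    zygosity = "MZ", sex = "male", wave = "w",
                    age = c(12, 12, 12.5), x = c(1, 2, 3))
  st <- descriptive_stats(tab, "x")
  expect_equal(st$mean, 2)
  expect_equal(st$sd, 1)
  one <- descriptive_stats(tab[1, ], "x")
  expect_true(is.na(one$sd))

  # recovery of the generating mean/SD at the built-in design's n
  trh <- reference_truth("height", "male", "intake")
  coh <- simulate_twins(mtfs_design(), trh, seed = 2024)
  st2 <- descriptive_stats(coh, "height")
  cell <- st2[st2$sex == "male" & st2$wave == "intake", ]
  se_mean <- 7.02 / sqrt(cell$n)
  expect_lt(abs(cell$mean - 149), 3 * se_mean)
  expect_lt(abs(cell$sd - 7.02), 3 * 7.02 / sqrt(2 * cell$n))
})
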