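#' Fit a univariate twin variance-components model by maximum likelihood
#'
#' Maximizes the two-group (MZ, DZ) multivariate-normal likelihood of twin
#' pair data under the classical decomposition: within-twin variance
#' a^2 + c^2 + e^2, MZ cross-twin covariance a^2 + c^2 and DZ cross-twin
#' covariance 0.5 a^2 + c^2, with one grand mean shared over twins and
#' zygosity groups. Path coefficients are constrained non-negative and the
#' unique-environmental path is kept strictly positive (it absorbs
#' measurement error, so e^2 > 0 by construction). Data are standardized
#' internally by the pooled phenotypic SD, which makes the reported
#' standardized components exactly invariant to affine rescaling of the
#' trait.
#'
#' The optimizer is quasi-Newton (L-BFGS-B) run from a moment-estimator
#' start plus deterministically jittered restarts; the best converged
#' solution is kept.
#'
#' @param pairs A univariate \code{\link{twin_pairs}} object. Pairs with a
#'   missing co-twin are used via full-information likelihood when present
#'   (build the pairs with \code{complete = FALSE}).
#' @param model One of \code{"ACE"}, \code{"AE"}, \code{"CE"}, \code{"E"}.
#' @param starts Number of optimizer starts (first is the moment start).
#' @return An object of class \code{"twin_fit"} with standardized components
#'   \code{a2, c2, e2} (summing to 1), path coefficients on the trait scale,
#'   \code{minus2LL}, \code{n_params}, and a convergence flag. Use
#'   \code{\link{confint.twin_fit}} for profile-likelihood intervals.
#' @examples
#' tr <- univariate_truth(0.6, 0.2, 0.2)
#' coh <- simulate_twins(pair_design(400, 200), tr, seed = 7)
#' fit <- twin_ace(twin_pairs(coh, "trait"), "ACE")
#' coef(fit)
#' @export
twin_ace <- function(pairs, model = c("ACE", "AE", "CE", "E"), starts = 5) {
  stopifnot(inherits(pairs, "twin_pairs"))
  if (pairs$k != 1) stop("twin_ace() fits one trait; see twin_cholesky()")
  model <- match.arg(model)
  need_both <- model %in% c("ACE", "AE", "CE")
  if ((nrow(pairs$mz) < 2 || nrow(pairs$dz) < 2) && need_both) {
    stop("at least 2 complete pairs per zygosity are required")
  }

  mom <- .pair_moments(pairs)
  s <- sqrt(mom$P[1, 1])
  mz <- pairs$mz / s
  dz <- pairs$dz / s
  st_mz <- .pair_stats(mz)
  st_dz <- .pair_stats(dz)

  # moment start on the standardized scale
  rmz <- if (!is.null(mom$mz)) mom$mz$X[1, 1] / mom$mz$W[1, 1] else 0
  rdz <- if (!is.null(mom$dz)) mom$dz$X[1, 1] / mom$dz$W[1, 1] else 0
  a2_0 <- min(max(2 * (rmz - rdz), 0.05), 0.9)
  c2_0 <- min(max(2 * rdz - rmz, 0.05), 0.9)
  e2_0 <- max(1 - a2_0 - c2_0, 0.05)
  tot <- a2_0 + c2_0 + e2_0
  mu0 <- mean(c(mz, dz), na.rm = TRUE)

  free <- switch(model,
                 ACE = c(TRUE, TRUE, TRUE),
                 AE  = c(TRUE, FALSE, TRUE),
                 CE  = c(FALSE, TRUE, TRUE),
                 E   = c(FALSE, FALSE, TRUE))
  emin <- 1e-6
  obj <- function(par) {
    paths <- c(0, 0, 0)
    paths[free] <- par[-1]
    a <- paths[1]; cc <- paths[2]; e <- paths[3]
    V <- a^2 + cc^2 + e^2
    Smz <- matrix(c(V, a^2 + cc^2, a^2 + cc^2, V), 2)
    Sdz <- matrix(c(V, 0.5 * a^2 + cc^2, 0.5 * a^2 + cc^2, V), 2)
    mu <- rep(par[1], 2)
    .neg2ll_patterns(st_mz, mu, Smz) + .neg2ll_patterns(st_dz, mu, Sdz)
  }

  p0 <- c(mu0, sqrt(c(a2_0, c2_0, e2_0) / tot)[free])
  jit <- c(1, 0.6, 1.5, 0.3, 2.0)[seq_len(min(max(1, starts), 5))]
  lower <- c(-Inf, ifelse(seq_len(sum(free)) == sum(free), emin, 0))
  best <- NULL
  for (j in jit) {
    p <- p0; p[-1] <- pmax(p0[-1] * j, lower[-1])
    op <- tryCatch(
      stats::optim(p, obj, method = "L-BFGS-B", lower = lower,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("optimization failed from every start")

  warn <- character()
  if (model == "ACE" && rdz > rmz) {
    warn <- c(warn, paste("DZ correlation exceeds MZ correlation;",
                          "c^2 driven to the zero boundary"))
  }
  paths_s <- c(0, 0, 0)
  paths_s[free] <- best$par[-1]
  V <- sum(paths_s^2)
  comps <- paths_s^2 / V
  names(comps) <- c("a2", "c2", "e2")
  fit <- list(
    model = model, trait = pairs$traits,
    mean = best$par[1] * s,
    paths = stats::setNames(paths_s * s, c("a", "c", "e")),
    components = comps,
    minus2LL = best$value + 2 * sum(vapply(c(st_mz, st_dz),
                                           function(x) x$n * length(x$idx),
                                           0)) * log(s),
    n_params = 1L + as.integer(sum(free)),
    converged = best$convergence == 0,
    n_pairs = c(MZ = nrow(pairs$mz), DZ = nrow(pairs$dz)),
    warnings = warn,
    .scaled = list(st_mz = st_mz, st_dz = st_dz, scale = s,
                   mu = best$par[1], free = free, value = best$value))
  for (w in warn) warning(w, call. = FALSE)
  class(fit) <- "twin_fit"
  fit
}

#' Fit the saturated two-group model
#'
#' Per zygosity group, all means, variances and covariances are free; the
#' maximum-likelihood solution is the sample moments (ML covariance), so the
#' fit is closed form. In the univariate two-group case this gives 10
#' parameters and the nesting benchmark for likelihood-ratio testing of the
#' structured models.
#'
#' @param pairs A \code{\link{twin_pairs}} object (any number of traits);
#'   incomplete pairs are dropped with a warning.
#' @return A \code{"twin_fit"} with model \code{"SAT"} and the fitted
#'   per-group moments.
#' @export
twin_saturated <- function(pairs) {
  stopifnot(inherits(pairs, "twin_pairs"))
  m <- 2 * pairs$k
  one <- function(X, zg) {
    drop_n <- sum(!stats::complete.cases(X))
    if (drop_n) warning(sprintf(
      "%d incomplete %s pair(s) dropped from the saturated fit", drop_n, zg))
    X <- X[stats::complete.cases(X), , drop = FALSE]
    if (nrow(X) < m) stop("too few complete pairs for a saturated fit")
    mu <- colMeans(X)
    S <- stats::cov(X) * (nrow(X) - 1) / nrow(X)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) stop("singular sample covariance in the ", zg, " group")
    list(mu = mu, S = S, n = nrow(X),
         neg2ll = nrow(X) * (m * log(2 * pi) + 2 * sum(log(diag(ch))) + m))
  }
  gmz <- one(pairs$mz, "MZ")
  gdz <- one(pairs$dz, "DZ")
  fit <- list(
    model = "SAT", trait = pairs$traits,
    moments = list(MZ = gmz[c("mu", "S")], DZ = gdz[c("mu", "S")]),
    minus2LL = gmz$neg2ll + gdz$neg2ll,
    n_params = as.integer(2 * (m + m * (m + 1) / 2)),
    converged = TRUE,
    n_pairs = c(MZ = gmz$n, DZ = gdz$n),
    warnings = character())
  class(fit) <- "twin_fit"
  fit
}

#' Likelihood-ratio test between nested twin models
#'
#' chi^2 is the difference in -2 log-likelihood, degrees of freedom the
#' difference in parameter counts, and the p-value the chi-square upper
#' tail. For single-df tests of a variance component against its zero
#' boundary the conventional chi-square p is reported (matching common
#' practice) and the 50:50 mixture-corrected p is carried alongside as
#' \code{p_mixture}.
#'
#' @param restricted,full Fits on the same data, restricted nested in full.
#' @return An object of class \code{"twin_lrt"} with chi2, df, p.
#' @export
twin_lrt <- function(restricted, full) {
  stopifnot(inherits(restricted, "twin_fit"), inherits(full, "twin_fit"))
  if (any(restricted$n_pairs != full$n_pairs)) {
    stop("fits do not use the same pair data")
  }
  df <- as.integer(full$n_params - restricted$n_params)
  if (df < 0) stop("'restricted' must have fewer parameters than 'full'")
  chi2 <- restricted$minus2LL - full$minus2LL
  if (chi2 < -1e-6) {
    warning("restricted fit beat the full fit; chi2 clamped to 0 ",
            "(full-model optimum not reached)")
  }
  chi2 <- max(chi2, 0)
  p <- if (df == 0) as.numeric(chi2 <= 1e-8) else
    stats::pchisq(chi2, df, lower.tail = FALSE)
  out <- list(chi2 = chi2, df = df, p = p,
              models = c(restricted$model, full$model))
  if (df == 1) {
    out$p_mixture <- 0.5 * stats::pchisq(chi2, 1, lower.tail = FALSE) +
      0.5 * (chi2 <= 1e-8)
  }
  class(out) <- "twin_lrt"
  out
}

#' @export
print.twin_lrt <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: chi2 = %.4f, df = %d, p = %.4g\n",
              x$models[1], x$models[2], x$chi2, x$df, x$p))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level.
#' @param m Number of tests (>= 1).
#' @return alpha / m.
#' @examples
#' bonferroni_threshold(0.05, 37)  # ~0.00135
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("'m' must be at least 1")
  alpha / m
}

# Profile -2 log-likelihood of one standardized component fixed at t, on the
# internally standardized scale. Remaining free quantities: grand mean,
# total variance, and (under ACE) the split of the remaining share.
.profile_share <- function(fit, comp, t) {
  sc <- fit$.scaled
  free <- sc$free
  model <- fit$model
  emin2 <- 1e-8
  shares <- function(w) {
    # returns c(a2, c2, e2) given the free remaining share w
    if (model == "ACE") {
      switch(comp,
             a2 = c(t, w, 1 - t - w),
             c2 = c(w, t, 1 - t - w),
             e2 = c(w, 1 - t - w, t))
    } else if (model == "AE") {
      switch(comp, a2 = c(t, 0, 1 - t), e2 = c(1 - t, 0, t),
             stop("c2 is fixed at 0 under the AE model"))
    } else if (model == "CE") {
      switch(comp, c2 = c(0, t, 1 - t), e2 = c(0, 1 - t, t),
             stop("a2 is fixed at 0 under the CE model"))
    } else stop("no free components under the E model")
  }
  has_w <- model == "ACE"
  obj <- function(par) {
    mu <- par[1]; V <- par[2]
    w <- if (has_w) par[3] else 0
    sh <- shares(w)
    if (any(sh < -1e-12) || sh[3] < emin2 || V <= 0) return(.BIG)
    cmz <- V * (sh[1] + sh[2]); cdz <- V * (0.5 * sh[1] + sh[2])
    Smz <- matrix(c(V, cmz, cmz, V), 2)
    Sdz <- matrix(c(V, cdz, cdz, V), 2)
    .neg2ll_patterns(sc$st_mz, rep(mu, 2), Smz) +
      .neg2ll_patterns(sc$st_dz, rep(mu, 2), Sdz)
  }
  est <- fit$components
  w0 <- if (has_w) switch(comp, a2 = est["c2"], c2 = est["a2"],
                          e2 = est["a2"]) else NULL
  wmax <- max(1 - t - emin2, 0)
  p0 <- c(sc$mu, 1, if (has_w) min(max(w0, 0), wmax))
  lower <- c(-Inf, 1e-8, if (has_w) 0)
  upper <- c(Inf, Inf, if (has_w) wmax)
  op <- tryCatch(
    stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(factr = 1e4, maxit = 300)),
    error = function(e) list(value = .BIG))
  op$value
}

#' Profile-likelihood confidence intervals for standardized components
#'
#' The interval for a component is the set of values whose profile
#' -2 log-likelihood lies within the chi-square(1) quantile (3.84 at 95
#' percent) of the minimum, clipped to [0, 1]; the lower bound is exactly 0
#' when the boundary is inside the region. A parametric-bootstrap
#' percentile interval is available as a fallback via
#' \code{method = "boot"}.
#'
#' @param object A structured \code{\link{twin_ace}} fit.
#' @param parm Components among \code{"a2"}, \code{"c2"}, \code{"e2"}
#'   (restricted to those free in the model).
#' @param level Confidence level.
#' @param method \code{"profile"} (default) or \code{"boot"}.
#' @param nboot Bootstrap replicates for \code{method = "boot"}.
#' @param seed Seed for the bootstrap.
#' @param ... Unused.
#' @return Matrix with columns \code{lower}, \code{upper}.
#' @export
confint.twin_fit <- function(object, parm = NULL, level = 0.95,
                             method = c("profile", "boot"), nboot = 1000,
                             seed = 1, ...) {
  method <- match.arg(method)
  if (object$model == "SAT") stop("intervals are for structured fits")
  if (!object$converged) warning("fit did not converge; intervals unreliable")
  avail <- switch(object$model, ACE = c("a2", "c2", "e2"),
                  AE = c("a2", "e2"), CE = c("c2", "e2"), E = "e2")
  if (is.null(parm)) parm <- avail
  parm <- match.arg(parm, avail, several.ok = TRUE)
  if (method == "boot") return(.boot_ci(object, parm, level, nboot, seed))
  thr <- object$.scaled$value + stats::qchisq(level, 1)
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  for (cp in parm) {
    est <- unname(object$components[cp])
    f <- function(t) .profile_share(object, cp, t) - thr
    lo <- if (est <= 1e-6 || f(0) <= 0) 0 else
      stats::uniroot(f, c(0, est), tol = 1e-4)$root
    tmax <- 1 - 1e-6
    hi <- if (est >= tmax || f(tmax) <= 0) 1 else
      stats::uniroot(f, c(est, tmax), tol = 1e-4)$root
    out[cp, ] <- c(max(0, lo), min(1, hi))
  }
  out
}

# Parametric bootstrap percentile intervals (fallback CI method).
.boot_ci <- function(fit, parm, level, nboot, seed) {
  set.seed(as.integer(seed))
  sh <- fit$components
  tr <- univariate_truth(sh["a2"], sh["c2"], sh["e2"],
                         total_var = sum(fit$paths^2))
  reps <- matrix(NA_real_, nboot, 3, dimnames = list(NULL, names(sh)))
  for (b in seq_len(nboot)) {
    prs <- .simulate_pairs(tr, fit$n_pairs["MZ"], fit$n_pairs["DZ"])
    rf <- tryCatch(twin_ace(prs, fit$model, starts = 1),
                   error = function(e) NULL)
    if (!is.null(rf)) reps[b, ] <- rf$components
  }
  al <- (1 - level) / 2
  t(vapply(parm, function(cp) {
    stats::quantile(reps[, cp], c(al, 1 - al), na.rm = TRUE, names = FALSE)
  }, numeric(2))) -> out
  dimnames(out) <- list(parm, c("lower", "upper"))
  out
}

# Internal: draw a twin_pairs object directly from a truth (no cohort table).
.simulate_pairs <- function(truth, n_mz, n_dz) {
  k <- length(truth$traits)
  lab <- truth$traits
  mz <- .rmvn(n_mz, implied_pair_covariance(truth, "MZ"))
  dz <- .rmvn(n_dz, implied_pair_covariance(truth, "DZ"))
  colnames(mz) <- colnames(dz) <- c(paste0(lab, ".1"), paste0(lab, ".2"))
  structure(list(mz = mz, dz = dz, traits = lab, k = k, complete = TRUE),
            class = "twin_pairs")
}
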