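#' Fit a multivariate Cholesky ACE/AE twin model
#'
#' The additive genetic, shared environmental and unique environmental
#' covariance matrices over k traits are parameterized through lower
#' triangular loading matrices X, Y, Z (A = XX', C = YY', E = ZZ'), which
#' keeps every implied component matrix positive semidefinite while
#' decomposing all covariation. The two-group likelihood has within-twin
#' blocks A + C + E and cross-twin blocks A + C (MZ) or 0.5 A + C (DZ), with
#' one grand mean per trait. The Cholesky factorization is a
#' parameterization, not a causal ordering: implied component matrices and
#' their correlations are invariant to trait order.
#'
#' Traits are standardized internally by their pooled phenotypic SDs and the
#' optimizer (BFGS, moment start plus deterministic restarts) works on the
#' standardized scale; estimates are returned on the trait scale.
#'
#' @param pairs A \code{\link{twin_pairs}} object over k traits (k = 1 is
#'   allowed and reproduces the univariate fit).
#' @param model \code{"ACE"} or \code{"AE"}.
#' @param starts Number of optimizer starts.
#' @return An object of class \code{"twin_chol"} with loading matrices
#'   \code{X}, \code{Y} (ACE only), \code{Z}, implied matrices \code{A},
#'   \code{C}, \code{E}, \code{minus2LL}, \code{n_params}, and a convergence
#'   flag.
#' @seealso \code{\link{component_correlations}},
#'   \code{\link{profile_corr_ci}}
#' @export
twin_cholesky <- function(pairs, model = c("ACE", "AE"), starts = 3) {
  stopifnot(inherits(pairs, "twin_pairs"))
  model <- match.arg(model)
  k <- pairs$k
  if (nrow(pairs$mz) < k + 2 || nrow(pairs$dz) < k + 2) {
    stop("at least k + 2 complete pairs per zygosity are required")
  }
  mom <- .pair_moments(pairs)
  if (min(eigen(.sym(mom$P), symmetric = TRUE,
                only.values = TRUE)$values) < 1e-10 * max(diag(mom$P))) {
    stop("ill-conditioned phenotypic covariance; traits are collinear")
  }
  s <- sqrt(diag(mom$P))
  sc2 <- c(s, s)
  mz <- sweep(pairs$mz, 2, sc2, "/")
  dz <- sweep(pairs$dz, 2, sc2, "/")
  st_mz <- .pair_stats(mz)
  st_dz <- .pair_stats(dz)

  D <- diag(1 / s, k)
  P0 <- D %*% mom$P %*% D
  Mx <- D %*% mom$mz$X %*% D
  Dx <- D %*% mom$dz$X %*% D
  if (model == "ACE") {
    A0 <- 2 * (Mx - Dx); C0 <- 2 * Dx - Mx
  } else {
    A0 <- Mx; C0 <- NULL
  }
  E0 <- P0 - Mx
  mu0 <- colMeans(rbind(mz[, seq_len(k), drop = FALSE],
                        mz[, k + seq_len(k), drop = FALSE],
                        dz[, seq_len(k), drop = FALSE],
                        dz[, k + seq_len(k), drop = FALSE]), na.rm = TRUE)
  eps0 <- 1e-3
  path0 <- c(.vech(.chol_lower(A0, eps0)),
             if (model == "ACE") .vech(.chol_lower(C0, eps0)),
             .vech(.chol_lower(E0, eps0)))

  obj <- .chol_objective(st_mz, st_dz, k, model)
  best <- NULL
  for (j in c(1, 0.85, 1.25)[seq_len(min(max(1, starts), 3))]) {
    op <- tryCatch(
      stats::optim(c(mu0, path0 * j), obj, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("optimization failed from every start")

  nl <- k * (k + 1) / 2
  mats <- .chol_unpack(best$par, k, model)
  Ds <- diag(s, k)
  lab <- pairs$traits
  X <- Ds %*% mats$X
  Z <- Ds %*% mats$Z
  Y <- if (model == "ACE") Ds %*% mats$Y else NULL
  A <- tcrossprod(X); E <- tcrossprod(Z)
  C <- if (model == "ACE") tcrossprod(Y) else matrix(0, k, k)
  dimnames(A) <- dimnames(C) <- dimnames(E) <- list(lab, lab)
  obs_log <- sum(vapply(c(st_mz, st_dz), function(x) {
    x$n * sum(log(s[(x$idx - 1) %% k + 1]))
  }, 0))
  fit <- list(
    model = model, traits = lab, k = k,
    means = stats::setNames(best$par[seq_len(k)] * s, lab),
    X = X, Y = Y, Z = Z, A = A, C = C, E = E,
    minus2LL = best$value + 2 * obs_log,
    n_params = as.integer(k + nl * (if (model == "ACE") 3 else 2)),
    converged = best$convergence == 0,
    n_pairs = c(MZ = nrow(pairs$mz), DZ = nrow(pairs$dz)),
    .scaled = list(st_mz = st_mz, st_dz = st_dz, scale = s, par = best$par,
                   value = best$value))
  class(fit) <- "twin_chol"
  fit
}

# par -> lower-triangular loading matrices on the standardized scale.
.chol_unpack <- function(par, k, model) {
  nl <- k * (k + 1) / 2
  off <- k
  X <- .unvech(par[off + seq_len(nl)], k); off <- off + nl
  Y <- NULL
  if (model == "ACE") {
    Y <- .unvech(par[off + seq_len(nl)], k); off <- off + nl
  }
  Z <- .unvech(par[off + seq_len(nl)], k)
  list(X = X, Y = Y, Z = Z)
}

.chol_objective <- function(st_mz, st_dz, k, model) {
  function(par) {
    m <- .chol_unpack(par, k, model)
    A <- tcrossprod(m$X)
    C <- if (model == "ACE") tcrossprod(m$Y) else matrix(0, k, k)
    E <- tcrossprod(m$Z)
    mu <- rep(par[seq_len(k)], 2)
    .neg2ll_patterns(st_mz, mu, .pair_sigma(A, C, E, "MZ")) +
      .neg2ll_patterns(st_dz, mu, .pair_sigma(A, C, E, "DZ"))
  }
}

#' @export
print.twin_chol <- function(x, ...) {
  cat(sprintf("Cholesky %s model over %d traits: %s\n", x$model, x$k,
              paste(x$traits, collapse = ", ")))
  cat(sprintf("  pairs: %d MZ, %d DZ;  -2lnL = %.3f (%d parameters)%s\n",
              x$n_pairs["MZ"], x$n_pairs["DZ"], x$minus2LL, x$n_params,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  P <- diag(x$A + x$C + x$E)
  comp <- rbind(a2 = diag(x$A) / P, c2 = diag(x$C) / P, e2 = diag(x$E) / P)
  print(round(comp, 3))
  invisible(x)
}

#' @export
logLik.twin_chol <- function(object, ...) {
  structure(-object$minus2LL / 2, df = object$n_params,
            nobs = sum(object$n_pairs), class = "logLik")
}

#' Standardized component correlations from a Cholesky fit
#'
#' Standardizes the implied A, C, E covariance matrices into the additive
#' genetic, shared environmental and unique environmental cross-trait
#' correlation matrices r_A, r_C, r_E. Entries whose diagonal component
#' variance is numerically zero are flagged undefined rather than
#' fabricated; correlations at the plus/minus 1 boundary carry a boundary
#' flag.
#'
#' @param fit A \code{\link{twin_cholesky}} fit.
#' @return An object of class \code{"component_corr"} with matrices
#'   \code{r_A}, \code{r_C} (NULL under AE), \code{r_E}, and logical
#'   \code{undefined} / \code{boundary} matrices per component.
#' @export
component_correlations <- function(fit) {
  stopifnot(inherits(fit, "twin_chol"))
  if (!fit$converged) warning("fit did not converge; correlations unreliable")
  mk <- function(M) {
    R <- .safe_cov2cor(M)
    list(r = R, undefined = is.na(R),
         boundary = !is.na(R) & abs(R) > 1 - 1e-8 &
           row(R) != col(R))
  }
  a <- mk(fit$A); e <- mk(fit$E)
  cc <- if (fit$model == "ACE") mk(fit$C) else NULL
  structure(list(r_A = a$r, r_C = cc$r, r_E = e$r,
                 undefined = list(A = a$undefined,
                                  C = cc$undefined, E = e$undefined),
                 boundary = list(A = a$boundary,
                                 C = cc$boundary, E = e$boundary),
                 model = fit$model, traits = fit$traits),
            class = "component_corr")
}

#' @export
print.component_corr <- function(x, digits = 2, ...) {
  cat(sprintf("Component correlations (%s model)\n", x$model))
  for (nm in c("r_A", "r_C", "r_E")) {
    if (is.null(x[[nm]])) next
    cat(nm, ":\n", sep = "")
    print(round(x[[nm]], digits))
  }
  invisible(x)
}

#' Profile-likelihood interval for a component correlation
#'
#' For a bivariate Cholesky fit, the chosen component matrix is
#' re-parameterized as standard deviations plus a correlation held fixed at
#' r, the remaining parameters are re-optimized, and the interval collects
#' the r values whose profile -2 log-likelihood stays within the
#' chi-square(1) quantile of the minimum. Bounds that never leave the
#' region are reported as plus/minus 1 (boundary), matching the typically
#' very wide shared-environmental correlation intervals at twin-study
#' sample sizes.
#'
#' @param fit A bivariate \code{\link{twin_cholesky}} fit.
#' @param component \code{"A"}, \code{"C"} (ACE fits only) or \code{"E"}.
#' @param level Confidence level.
#' @param ngrid Number of grid points for the profile walk.
#' @return Length-2 vector (lower, upper) with the profile curve attached
#'   as attribute \code{"profile"}.
#' @export
profile_corr_ci <- function(fit, component = c("A", "C", "E"), level = 0.95,
                            ngrid = 25) {
  stopifnot(inherits(fit, "twin_chol"))
  component <- match.arg(component)
  if (fit$k != 2) stop("profile correlation intervals are bivariate")
  if (component == "C" && fit$model != "ACE") {
    stop("the AE model has no shared-environmental correlation")
  }
  sc <- fit$.scaled
  k <- 2
  comp_mat <- switch(component, A = fit$A, C = fit$C, E = fit$E)
  Rhat <- .safe_cov2cor(comp_mat)[1, 2]
  if (is.na(Rhat)) {
    warning("component variance numerically zero; correlation undefined")
    return(c(NA_real_, NA_real_))
  }
  D <- diag(1 / sc$scale, k)
  others <- setdiff(c("A", if (fit$model == "ACE") "C", "E"), component)
  start_other <- lapply(others, function(nm) {
    .vech(.chol_lower(D %*% fit[[nm]] %*% D, 1e-6))
  })
  Wsc <- D %*% comp_mat %*% D
  s0 <- sqrt(pmax(diag(Wsc), 1e-6))
  mu0 <- sc$par[seq_len(k)]

  obj_r <- function(par, r) {
    mu <- rep(par[1:2], 2)
    s1 <- par[3]; s2 <- par[4]
    W <- matrix(c(s1^2, r * s1 * s2, r * s1 * s2, s2^2), 2)
    off <- 4
    oth <- list()
    for (i in seq_along(others)) {
      L <- .unvech(par[off + 1:3], 2); off <- off + 3
      oth[[others[i]]] <- tcrossprod(L)
    }
    A <- if (component == "A") W else oth$A
    C <- if (component == "C") W else
      if (fit$model == "ACE") oth$C else matrix(0, 2, 2)
    E <- if (component == "E") W else oth$E
    .neg2ll_patterns(sc$st_mz, mu, .pair_sigma(A, C, E, "MZ")) +
      .neg2ll_patterns(sc$st_dz, mu, .pair_sigma(A, C, E, "DZ"))
  }
  lower_b <- c(-Inf, -Inf, 1e-8, 1e-8, rep(-Inf, 3 * length(others)))
  pll <- function(r, p_start) {
    run <- function(p) tryCatch(
      stats::optim(p, obj_r, r = r, method = "L-BFGS-B", lower = lower_b,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) list(value = .BIG, par = p))
    op <- run(p_start)
    # cold restart guards against plateaus trapping the warm-started walk
    op2 <- run(c(mu0, s0, unlist(start_other)))
    if (op2$value < op$value) op <- op2
    list(value = op$value, par = op$par)
  }

  p0 <- c(mu0, s0, unlist(start_other))
  rmax <- 0.999
  grid <- sort(unique(c(seq(-rmax, rmax, length.out = ngrid),
                        min(max(Rhat, -rmax), rmax))))
  i0 <- which.min(abs(grid - Rhat))
  vals <- numeric(length(grid))
  pars <- vector("list", length(grid))
  walk <- function(idx_seq) {
    p <- p0
    for (i in idx_seq) {
      res <- pll(grid[i], p)
      vals[i] <<- res$value
      pars[[i]] <<- p <- res$par
    }
  }
  walk(i0:1)
  if (i0 < length(grid)) walk((i0 + 1):length(grid))

  mval <- min(c(vals, sc$value))
  thr <- mval + stats::qchisq(level, 1)
  inside <- vals <= thr
  if (!any(inside)) return(c(NA_real_, NA_real_))
  lo_i <- min(which(inside)); hi_i <- max(which(inside))
  refine <- function(i_out, i_in) {
    f <- function(r) pll(r, pars[[i_in]])$value - thr
    stats::uniroot(f, c(grid[i_out], grid[i_in]), tol = 1e-3,
                   f.lower = vals[i_out] - thr,
                   f.upper = vals[i_in] - thr)$root
  }
  lo <- if (lo_i == 1) -1 else refine(lo_i - 1, lo_i)
  hi <- if (hi_i == length(grid)) 1 else refine(hi_i, hi_i + 1)
  structure(c(lower = lo, upper = hi),
            profile = data.frame(r = grid, neg2ll = vals))
}

#' Pairwise genetic-correlation matrix over a trait set
#'
#' Runs the bivariate AE fit for every unordered trait pair, then the ACE
#' fit for confirmation (shared-environmental variance is typically too
#' small to move the genetic correlations much), and assembles the
#' additive-genetic, shared-environmental and unique-environmental
#' correlation matrices. Pairwise failures are recorded and skipped; they
#' never abort the remaining pairs.
#'
#' @param table Preprocessed cohort data frame.
#' @param traits Trait columns (k >= 2).
#' @param sex,wave Stratum selectors passed to \code{\link{twin_pairs}}.
#' @param models Character vector among \code{"AE"}, \code{"ACE"}; both by
#'   default (AE first, ACE confirmation).
#' @return An object of class \code{"gcor_matrix"} with matrices
#'   \code{r_A_AE}, \code{r_A_ACE}, \code{r_C_ACE}, \code{r_E_ACE},
#'   \code{delta_r_A} (ACE minus AE) and a data frame \code{failures}.
#' @export
genetic_correlation_matrix <- function(table, traits, sex = NULL,
                                       wave = NULL,
                                       models = c("AE", "ACE")) {
  k <- length(traits)
  if (k < 2) stop("need at least two traits")
  models <- match.arg(models, c("AE", "ACE"), several.ok = TRUE)
  mk <- function() matrix(NA_real_, k, k, dimnames = list(traits, traits))
  out <- list(r_A_AE = mk(), r_A_ACE = mk(), r_C_ACE = mk(), r_E_ACE = mk())
  for (m in names(out)) diag(out[[m]]) <- 1
  fails <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      prs <- tryCatch(twin_pairs(table, c(traits[i], traits[j]), sex = sex,
                                 wave = wave),
                      error = function(e) e)
      if (inherits(prs, "error")) {
        fails[[length(fails) + 1]] <- data.frame(
          trait1 = traits[i], trait2 = traits[j], model = "(pairs)",
          message = conditionMessage(prs))
        next
      }
      for (m in models) {
        res <- tryCatch(suppressWarnings({
          cc <- component_correlations(twin_cholesky(prs, m))
          if (m == "AE") {
            out$r_A_AE[i, j] <- out$r_A_AE[j, i] <- cc$r_A[1, 2]
          } else {
            out$r_A_ACE[i, j] <- out$r_A_ACE[j, i] <- cc$r_A[1, 2]
            out$r_C_ACE[i, j] <- out$r_C_ACE[j, i] <- cc$r_C[1, 2]
            out$r_E_ACE[i, j] <- out$r_E_ACE[j, i] <- cc$r_E[1, 2]
          }
          NULL
        }), error = function(e) e)
        if (inherits(res, "error")) {
          fails[[length(fails) + 1]] <- data.frame(
            trait1 = traits[i], trait2 = traits[j], model = m,
            message = conditionMessage(res))
        }
      }
    }
  }
  out$delta_r_A <- out$r_A_ACE - out$r_A_AE
  out$failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(trait1 = character(), trait2 = character(),
               model = character(), message = character())
  out$traits <- traits
  class(out) <- "gcor_matrix"
  out
}

#' @export
print.gcor_matrix <- function(x, digits = 2, ...) {
  cat("Pairwise genetic correlations over", length(x$traits), "traits\n")
  cat("r_A (AE model):\n"); print(round(x$r_A_AE, digits))
  if (any(is.finite(x$r_A_ACE[upper.tri(x$r_A_ACE)]))) {
    cat("r_A (ACE confirmation):\n"); print(round(x$r_A_ACE, digits))
  }
  if (nrow(x$failures)) {
    cat(nrow(x$failures), "pairwise fit(s) failed and were skipped\n")
  }
  invisible(x)
}

#' Cross-wave trait, genetic and environmental correlations
#'
#' The phenotypic cross-wave correlation is computed on individuals with
#' complete data at both waves (one entry per person); the additive genetic
#' and unique environmental cross-wave correlations come from a bivariate
#' Cholesky fit treating the wave-1 and wave-2 measurements of the trait as
#' two traits.
#'
#' @param table Preprocessed cohort data frame.
#' @param trait Trait column measured at both waves.
#' @param sex Sex stratum.
#' @param waves Length-2 wave labels; default the table's first two waves.
#' @param model \code{"ACE"} (default) or \code{"AE"} for the Cholesky fit.
#' @param ci Also compute profile intervals for r_A and r_E.
#' @param level Confidence level.
#' @return An object of class \code{"crosswave_cor"}: phenotypic \code{r}
#'   with Fisher-z interval, \code{r_A}, \code{r_E} (and \code{r_C} under
#'   ACE), the underlying fit, and optional profile intervals.
#' @export
cross_wave_correlations <- function(table, trait, sex = NULL, waves = NULL,
                                    model = c("ACE", "AE"), ci = FALSE,
                                    level = 0.95) {
  model <- match.arg(model)
  if (is.null(waves)) {
    waves <- unique(table$wave)
    if (length(waves) < 2) stop("table has fewer than two waves")
    waves <- waves[1:2]
  }
  tab <- if (is.null(sex)) table else table[table$sex %in% sex, , drop = FALSE]
  w1 <- tab[tab$wave == waves[1], c("family_id", "twin_index", trait)]
  w2 <- tab[tab$wave == waves[2], c("family_id", "twin_index", trait)]
  both <- merge(w1, w2, by = c("family_id", "twin_index"),
                suffixes = c(".w1", ".w2"))
  both <- both[stats::complete.cases(both), , drop = FALSE]
  if (nrow(both) < 3) stop("fewer than 3 individuals measured at both waves")
  x <- both[[paste0(trait, ".w1")]]
  y <- both[[paste0(trait, ".w2")]]
  r <- stats::cor(x, y)
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  r_ci <- if (abs(r) >= 1) c(r, r) else
    tanh(atanh(r) + c(-1, 1) * zcrit / sqrt(nrow(both) - 3))

  prs <- twin_pairs(table, c(trait, trait), sex = sex, waves = waves)
  fit <- tryCatch(twin_cholesky(prs, model), error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(trait = trait, waves = waves, r = r, r_ci = r_ci,
                n_individuals = nrow(both), r_A = NA_real_, r_E = NA_real_,
                r_C = NA_real_, fit = NULL,
                fit_error = conditionMessage(fit))
    class(out) <- "crosswave_cor"
    return(out)
  }
  cc <- component_correlations(fit)
  out <- list(trait = trait, waves = waves, r = r, r_ci = r_ci,
              n_individuals = nrow(both),
              r_A = cc$r_A[1, 2], r_E = cc$r_E[1, 2],
              r_C = if (model == "ACE") cc$r_C[1, 2] else NA_real_,
              fit = fit, fit_error = NULL)
  if (ci) {
    out$r_A_ci <- profile_corr_ci(fit, "A", level)
    out$r_E_ci <- profile_corr_ci(fit, "E", level)
  }
  class(out) <- "crosswave_cor"
  out
}

#' @export
print.crosswave_cor <- function(x, ...) {
  cat(sprintf("Cross-wave correlations for %s (%s -> %s)\n", x$trait,
              x$waves[1], x$waves[2]))
  cat(sprintf("  phenotypic r = %.3f [%.3f, %.3f] (n = %d individuals)\n",
              x$r, x$r_ci[1], x$r_ci[2], x$n_individuals))
  if (!is.null(x$fit_error)) {
    cat("  component fit failed:", x$fit_error, "\n")
  } else {
    cat(sprintf("  r_A = %.3f   r_E = %.3f%s\n", x$r_A, x$r_E,
                if (is.na(x$r_C)) "" else sprintf("   r_C = %.3f", x$r_C)))
  }
  invisible(x)
}
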