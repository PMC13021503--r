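# Multivariate-normal -2 log-likelihood machinery shared by the saturated,
# univariate and Cholesky twin fits. Data enter through per-missingness-
# pattern sufficient statistics, so objective evaluations cost O(k^3)
# regardless of sample size and partially observed pairs are handled by
# marginalizing the missing elements (full-information likelihood).

.BIG <- 1e12

# Group rows of a pair matrix (n x 2k, possibly with NAs) by missingness
# pattern; per pattern keep n, the mean vector and the ML (divisor n)
# covariance about it.
.pair_stats <- function(X) {
  if (!nrow(X)) return(list())
  obs <- !is.na(X)
  key <- apply(obs, 1, function(z) paste0(as.integer(z), collapse = ""))
  out <- list()
  for (kk in unique(key)) {
    rows <- which(key == kk)
    idx <- which(obs[rows[1], ])
    if (!length(idx)) next
    Y <- X[rows, idx, drop = FALSE]
    n <- nrow(Y)
    ybar <- colMeans(Y)
    Yc <- sweep(Y, 2, ybar)
    out[[length(out) + 1]] <- list(idx = idx, n = n, ybar = ybar,
                                   S = crossprod(Yc) / n)
  }
  out
}

# -2 log-likelihood of all patterns under mean vector mu (length 2k) and
# covariance Sigma (2k x 2k).
.neg2ll_patterns <- function(stats, mu, Sigma) {
  tot <- 0
  for (st in stats) {
    m <- length(st$idx)
    Sg <- Sigma[st$idx, st$idx, drop = FALSE]
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(.BIG)
    logdet <- 2 * sum(log(diag(ch)))
    Si <- chol2inv(ch)
    d <- st$ybar - mu[st$idx]
    tot <- tot + st$n * (m * log(2 * pi) + logdet + sum(Si * st$S) +
                           drop(crossprod(d, Si %*% d)))
  }
  if (!is.finite(tot)) return(.BIG)
  tot
}

# Implied 2k x 2k pair covariance from component matrices.
.pair_sigma <- function(A, C, E, zygosity) {
  P <- A + C + E
  cross <- if (zygosity == "MZ") A + C else 0.5 * A + C
  rbind(cbind(P, cross), cbind(cross, P))
}

# Moment summaries of pair data used for starting values and the closed-form
# moment estimator: pooled within-twin covariance plus symmetrized cross-twin
# covariance per zygosity (complete pairs only).
.pair_moments <- function(pairs) {
  k <- pairs$k
  blocks <- function(X) {
    X <- X[stats::complete.cases(X), , drop = FALSE]
    if (nrow(X) < 2) return(NULL)
    S <- stats::cov(X) * (nrow(X) - 1) / nrow(X)
    W <- (S[seq_len(k), seq_len(k), drop = FALSE] +
            S[k + seq_len(k), k + seq_len(k), drop = FALSE]) / 2
    Xb <- .sym(S[seq_len(k), k + seq_len(k), drop = FALSE])
    list(W = W, X = Xb, n = nrow(X))
  }
  mz <- blocks(pairs$mz)
  dz <- blocks(pairs$dz)
  W <- if (!is.null(mz) && !is.null(dz)) {
    (mz$n * mz$W + dz$n * dz$W) / (mz$n + dz$n)
  } else if (!is.null(mz)) mz$W else dz$W
  list(mz = mz, dz = dz, P = W)
}
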