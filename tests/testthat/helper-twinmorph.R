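# Shared fixtures for the twinmorph test suite. All data are generated in
# code; `exact_mvn` produces samples whose ML sample moments equal their
# targets exactly, which turns optimizer self-consistency checks into sharp
# assertions.

# n draws with sample mean exactly `mu` and ML (divisor n) covariance
# exactly `Sigma`.
exact_mvn <- function(n, Sigma, mu = rep(0, ncol(Sigma))) {
  m <- ncol(Sigma)
  X <- matrix(stats::rnorm(n * m), n, m)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  Z <- Xc %*% solve(chol(S))
  sweep(Z %*% chol(Sigma), 2, mu, "+")
}

# twin_pairs object built directly from matrices (bypasses the cohort table)
as_twin_pairs <- function(mz, dz, traits = paste0("t", seq_len(ncol(mz) / 2))) {
  k <- length(traits)
  colnames(mz) <- colnames(dz) <- c(paste0(traits, ".1"), paste0(traits, ".2"))
  structure(list(mz = mz, dz = dz, traits = traits, k = k, complete = TRUE),
            class = "twin_pairs")
}

# pair data whose sample moments equal the implied ACE moments exactly
moment_matched_pairs <- function(n_mz, n_dz, a2, c2, e2 = 1 - a2 - c2,
                                 V = 1, mu = 0) {
  smz <- V * matrix(c(1, a2 + c2, a2 + c2, 1), 2)
  sdz <- V * matrix(c(1, 0.5 * a2 + c2, 0.5 * a2 + c2, 1), 2)
  as_twin_pairs(exact_mvn(n_mz, smz, rep(mu, 2)),
                exact_mvn(n_dz, sdz, rep(mu, 2)), "t")
}

# closed-form moment estimator of the ACE components from double-entry
# co-twin correlations: the independent oracle for the ML fits
moment_ace <- function(pairs) {
  cc <- cotwin_correlations(pairs)
  rmz <- cc$r[cc$zygosity == "MZ"]
  rdz <- cc$r[cc$zygosity == "DZ"]
  c(a2 = 2 * (rmz - rdz), c2 = 2 * rdz - rmz, e2 = 1 - rmz)
}

# random PSD matrix via Wishart-style construction
random_psd <- function(k, scale = 1) {
  G <- matrix(stats::rnorm(k * (k + 2)), k + 2, k)
  crossprod(G) / (k + 2) * scale
}

# block correlation matrix: `nb` blocks of `p` traits, `within` inside and
# `between` across blocks
block_corr <- function(p, nb, within = 0.7, between = 0.2) {
  k <- p * nb
  M <- matrix(between, k, k)
  for (b in seq_len(nb)) {
    i <- ((b - 1) * p + 1):(b * p)
    M[i, i] <- within
  }
  diag(M) <- 1
  M
}
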