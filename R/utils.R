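# Small numerical helpers shared across the fitting code.

.SEXES <- c("male", "female")
.ZYGOSITIES <- c("MZ", "DZ")
.ID_COLS <- c("family_id", "twin_index", "zygosity", "sex", "wave", "age")

.vech <- function(M) M[lower.tri(M, diag = TRUE)]

.unvech <- function(v, k) {
  L <- matrix(0, k, k)
  L[lower.tri(L, diag = TRUE)] <- v
  L
}

.sym <- function(M) (M + t(M)) / 2

.min_eigen <- function(M) {
  min(eigen(.sym(M), symmetric = TRUE, only.values = TRUE)$values)
}

# Symmetry / positive-semidefiniteness guard used on all user-supplied
# component matrices.
.check_psd <- function(M, name, tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  }
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M)))) {
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  }
  if (.min_eigen(M) < -tol * max(1, max(abs(diag(M))))) {
    stop(sprintf("'%s' must be positive semidefinite", name), call. = FALSE)
  }
  invisible(TRUE)
}

# Eigenvalue clipping onto the PSD cone; used for optimizer starting values,
# never for reported estimates.
.psd_project <- function(M, eps = 1e-8) {
  e <- eigen(.sym(M), symmetric = TRUE)
  d <- pmax(e$values, eps)
  .sym(e$vectors %*% (d * t(e$vectors)))
}

.chol_lower <- function(M, eps = 1e-8) {
  t(chol(.psd_project(M, eps)))
}

# Correlation matrix from a PSD covariance matrix with guards for vanishing
# diagonal variances (entries flagged NA rather than fabricated).
.safe_cov2cor <- function(M, tol = 1e-10) {
  d <- diag(M)
  bad <- d < tol
  s <- sqrt(ifelse(bad, NA_real_, d))
  R <- M / outer(s, s)
  R[bad, ] <- NA_real_
  R[, bad] <- NA_real_
  R <- pmin(pmax(R, -1), 1)
  diag(R) <- ifelse(bad, NA_real_, 1)
  R
}

.rmvn <- function(n, Sigma) {
  m <- ncol(Sigma)
  if (n == 0) return(matrix(numeric(0), 0, m))
  X <- MASS::mvrnorm(n, rep(0, m), Sigma, tol = 1e-6)
  if (n == 1) X <- matrix(X, 1, m)
  X
}
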