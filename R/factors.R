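#' Principal-factor analysis with optional varimax rotation
#'
#' Iterated principal-axis factoring of a correlation matrix: communalities
#' are initialized at squared multiple correlations, the diagonal is
#' replaced, loadings are taken from the top eigenpairs of the reduced
#' matrix, and the cycle repeats until the communalities stabilize.
#' Heywood cases (communalities above 1) are clipped and flagged. Rotation
#' is orthogonal varimax with Kaiser normalization, which leaves the
#' communalities and the reproduced correlation matrix unchanged. Columns
#' are sign-flipped so the largest-magnitude loading is positive and
#' ordered by explained sum of squared loadings.
#'
#' @param corr Symmetric correlation matrix (unit diagonal, PSD within
#'   tolerance).
#' @param n_factors Number of factors, 1 <= n_factors < ncol(corr).
#' @param rotation \code{"varimax"} (default, needs >= 2 factors) or
#'   \code{"none"}.
#' @param max_iter,tol Iteration cap and communality convergence tolerance.
#' @return An object of class \code{"factor_solution"}: \code{loadings}
#'   (traits x factors), \code{communalities}, \code{uniqueness},
#'   \code{iterations}, \code{converged}, \code{heywood}, \code{rotation},
#'   and \code{fit_history} (Frobenius distance between the off-diagonal of
#'   the input and reproduced correlations per iteration).
#' @examples
#' lam <- rep(0.8, 6)
#' R <- tcrossprod(lam) + diag(1 - lam^2)
#' principal_factor(R, 1)$loadings
#' @export
principal_factor <- function(corr, n_factors, rotation = c("varimax", "none"),
                             max_iter = 200, tol = 1e-6) {
  rotation <- match.arg(rotation)
  p <- ncol(corr)
  if (is.null(rownames(corr))) rownames(corr) <- paste0("trait", seq_len(p))
  traits <- rownames(corr)
  if (max(abs(corr - t(corr))) > 1e-8 || max(abs(diag(corr) - 1)) > 1e-6) {
    stop("'corr' must be a symmetric correlation matrix with unit diagonal")
  }
  if (.min_eigen(corr) < -1e-6) stop("'corr' is not positive semidefinite")
  if (n_factors < 1 || n_factors >= p) {
    stop("'n_factors' must satisfy 1 <= n_factors < ncol(corr)")
  }

  # squared multiple correlations; fall back to the largest absolute
  # off-diagonal correlation per row when the matrix is near singular
  comm <- tryCatch(1 - 1 / diag(solve(corr)), error = function(e) {
    apply(abs(corr - diag(p)), 1, max)
  })
  comm <- pmin(pmax(comm, 0), 1)
  heywood <- FALSE
  converged <- FALSE
  hist <- numeric()
  L <- matrix(0, p, n_factors)
  off <- !diag(p)
  for (it in seq_len(max_iter)) {
    Rred <- corr
    diag(Rred) <- comm
    e <- eigen(.sym(Rred), symmetric = TRUE)
    d <- pmax(e$values[seq_len(n_factors)], 0)
    L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(d), n_factors)
    new_comm <- rowSums(L^2)
    if (any(new_comm > 1)) {
      heywood <- TRUE
      scl <- sqrt(pmin(1, 1 / new_comm))
      L <- L * scl
      new_comm <- rowSums(L^2)
    }
    hist <- c(hist, sqrt(sum((corr[off] - tcrossprod(L)[off])^2)))
    if (max(abs(new_comm - comm)) < tol) {
      comm <- new_comm
      converged <- TRUE
      break
    }
    comm <- new_comm
  }

  if (rotation == "varimax" && n_factors >= 2 && any(comm > 1e-12)) {
    L <- stats::varimax(L, normalize = TRUE)$loadings[, , drop = FALSE]
    L <- matrix(as.numeric(L), p, n_factors)
  }
  # sign convention and ordering by explained variance
  for (f in seq_len(n_factors)) {
    if (L[which.max(abs(L[, f])), f] < 0) L[, f] <- -L[, f]
  }
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  dimnames(L) <- list(traits, paste0("F", seq_len(n_factors)))

  structure(list(loadings = L,
                 communalities = stats::setNames(rowSums(L^2), traits),
                 uniqueness = stats::setNames(1 - rowSums(L^2), traits),
                 n_factors = n_factors, rotation = rotation,
                 iterations = it, converged = converged, heywood = heywood,
                 fit_history = hist),
            class = "factor_solution")
}

# Raw varimax criterion: sum over factors of the variance of squared
# loadings. Used to verify that rotation does not decrease the criterion.
.varimax_criterion <- function(L) {
  sum(apply(L^2, 2, function(x) mean(x^2) - mean(x)^2))
}

#' @export
print.factor_solution <- function(x, digits = 3, cutoff = 0, ...) {
  cat(sprintf("Principal-factor solution: %d factors, %s rotation (%d %s)\n",
              x$n_factors, x$rotation, x$iterations,
              if (x$converged) "iterations" else "iterations, NOT converged"))
  if (x$heywood) cat("note: Heywood case encountered; communalities clipped\n")
  tab <- cbind(round(x$loadings, digits), h2 = round(x$communalities, digits))
  print(tab)
  invisible(x)
}
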