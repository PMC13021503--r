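#' Arrange a cohort table as per-pair observation vectors
#'
#' Reshapes individual rows to one stacked vector per family, ordered
#' (twin 1 traits, twin 2 traits) with twins ordered by stored
#' \code{twin_index} (never by value). For cross-wave analyses, supply one
#' wave per trait so that e.g. height at intake and height at follow-up form
#' a bivariate observation.
#'
#' @param table Cohort data frame.
#' @param traits Character vector of trait columns (length k).
#' @param sex Optional sex filter.
#' @param wave Single wave used for every trait (ignored when \code{waves}
#'   is given); defaults to the table's only wave.
#' @param waves Optional character vector, one wave per trait.
#' @param complete Keep only pairs with all 2k elements observed (default).
#'   With \code{FALSE}, pairs with at least one observed element are kept
#'   with NA masks for full-information likelihood fitting.
#' @return An object of class \code{"twin_pairs"}: matrices \code{mz} and
#'   \code{dz} (one row per pair, 2k columns) plus trait labels.
#' @export
twin_pairs <- function(table, traits, sex = NULL, wave = NULL, waves = NULL,
                       complete = TRUE) {
  k <- length(traits)
  if (!is.null(sex)) table <- table[table$sex %in% sex, , drop = FALSE]
  if (!nrow(table)) stop("no rows in the requested stratum")
  if (is.null(waves)) {
    if (is.null(wave)) {
      uw <- unique(table$wave)
      if (length(uw) != 1) stop("table has several waves; specify 'wave'")
      wave <- uw
    }
    waves <- rep(wave, k)
  }
  if (length(waves) != k) stop("'waves' must have one label per trait")
  if (!nrow(table)) stop("no rows in the requested stratum")

  fams <- sort(unique(table$family_id))
  zyg <- table$zygosity[match(fams, table$family_id)]
  key <- paste(table$family_id, table$wave, table$twin_index)
  X <- matrix(NA_real_, length(fams), 2 * k)
  lab <- if (length(unique(waves)) == 1) traits else paste0(traits, "@", waves)
  colnames(X) <- c(paste0(lab, ".1"), paste0(lab, ".2"))
  for (tw in 1:2) {
    for (i in seq_len(k)) {
      idx <- match(paste(fams, waves[i], tw), key)
      X[, (tw - 1) * k + i] <- table[[traits[i]]][idx]
    }
  }
  if (complete) {
    keep <- stats::complete.cases(X)
  } else {
    keep <- rowSums(!is.na(X)) > 0
  }
  X <- X[keep, , drop = FALSE]
  zyg <- zyg[keep]
  out <- list(mz = X[zyg == "MZ", , drop = FALSE],
              dz = X[zyg == "DZ", , drop = FALSE],
              traits = lab, k = k, complete = complete)
  if (!nrow(out$mz) && !nrow(out$dz)) stop("no pairs in the requested stratum")
  class(out) <- "twin_pairs"
  out
}

#' @export
print.twin_pairs <- function(x, ...) {
  cat(sprintf("Twin pair data: %d trait(s) [%s]\n", x$k,
              paste(x$traits, collapse = ", ")))
  cat(sprintf("  MZ pairs: %d   DZ pairs: %d   (%s)\n",
              nrow(x$mz), nrow(x$dz),
              if (x$complete) "complete pairs" else "with missingness masks"))
  invisible(x)
}

#' Co-twin correlations by double entry
#'
#' The correlation between co-twin values computed with each pair entered in
#' both orderings (an intraclass formulation that removes arbitrary twin
#' labelling), per zygosity group, with a Fisher-z 95 percent interval using
#' the number of pairs as the effective sample size.
#'
#' @param pairs A univariate \code{\link{twin_pairs}} object.
#' @param level Confidence level.
#' @return Data frame with zygosity, r, lower, upper, n_pairs.
#' @export
cotwin_correlations <- function(pairs, level = 0.95) {
  stopifnot(inherits(pairs, "twin_pairs"))
  if (pairs$k != 1) stop("co-twin correlations are defined per single trait")
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  one <- function(X, zg) {
    X <- X[stats::complete.cases(X), , drop = FALSE]
    n <- nrow(X)
    if (n == 0) return(NULL)
    if (n < 3) stop(sprintf("fewer than 3 complete %s pairs", zg))
    x <- c(X[, 1], X[, 2]); y <- c(X[, 2], X[, 1])
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning(sprintf("zero variance in %s group; correlation undefined", zg))
      return(data.frame(zygosity = zg, r = NA_real_, lower = NA_real_,
                        upper = NA_real_, n_pairs = n))
    }
    r <- stats::cor(x, y)
    if (abs(r) >= 1) {
      lo <- hi <- r
    } else {
      z <- atanh(r); se <- 1 / sqrt(n - 3)
      lo <- tanh(z - zcrit * se); hi <- tanh(z + zcrit * se)
    }
    data.frame(zygosity = zg, r = r, lower = lo, upper = hi, n_pairs = n)
  }
  rbind(one(pairs$mz, "MZ"), one(pairs$dz, "DZ"))
}
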