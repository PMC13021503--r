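#' Generative truth for twin-cohort simulation
#'
#' Bundles the additive genetic (A), shared environmental (C) and unique
#' environmental (E) covariance matrices with per-sex means and linear age
#' slopes. The phenotypic covariance is P = A + C + E; the within-pair
#' structure follows the classical twin design (A correlated 1 within MZ and
#' 0.5 within DZ pairs, C correlated 1 within both, E uncorrelated).
#'
#' @param A,C,E Symmetric positive-semidefinite covariance matrices (trait
#'   units squared), all of the same dimension. Scalars are accepted for a
#'   single trait.
#' @param traits Character vector of trait names.
#' @param means Per-trait, per-sex intercepts: a scalar, a length-k vector
#'   (recycled over sexes) or a k x 2 matrix with columns male, female. For
#'   traits in \code{lognormal} this is the mean on the log scale.
#' @param age_slopes Linear age coefficients (trait units per year), same
#'   shapes as \code{means}.
#' @param lognormal Character subset of \code{traits} generated on the log
#'   scale and exponentiated after the linear stage.
#' @param trait_wave Optional character vector (same length as
#'   \code{traits}) assigning each trait to a wave label, used for stacked
#'   cross-wave truths where e.g. \code{height} at intake and follow-up are
#'   two correlated traits of one joint distribution.
#' @return An object of class \code{"ace_truth"}.
#' @seealso \code{\link{univariate_truth}}, \code{\link{crosswave_truth}},
#'   \code{\link{implied_pair_covariance}}
#' @export
ace_truth <- function(A, C, E, traits = NULL, means = 0, age_slopes = 0,
                      lognormal = character(), trait_wave = NULL) {
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, 1, 1)
  A <- as_mat(A); C <- as_mat(C); E <- as_mat(E)
  k <- nrow(A)
  if (is.null(traits)) {
    traits <- rownames(A)
    if (is.null(traits)) traits <- paste0("trait", seq_len(k))
  }
  if (length(traits) != k) stop("'traits' must match the matrix dimension")
  if (nrow(C) != k || nrow(E) != k) stop("A, C, E must share one dimension")
  .check_psd(A, "A"); .check_psd(C, "C"); .check_psd(E, "E")
  P <- A + C + E
  if (any(diag(P) <= 0)) {
    stop("total phenotypic variance must be strictly positive for every trait")
  }
  if (!all(lognormal %in% traits)) {
    stop("'lognormal' must be a subset of 'traits'")
  }
  if (!is.null(trait_wave) && length(trait_wave) != k) {
    stop("'trait_wave' must have one wave label per trait")
  }
  dimnames(A) <- dimnames(C) <- dimnames(E) <- list(traits, traits)
  structure(
    list(traits = traits, A = A, C = C, E = E,
         means = .per_sex(means, k, traits),
         age_slopes = .per_sex(age_slopes, k, traits),
         lognormal = lognormal, trait_wave = trait_wave),
    class = "ace_truth")
}

.per_sex <- function(x, k, traits) {
  if (is.matrix(x)) {
    if (nrow(x) != k || ncol(x) != 2) stop("per-sex values must be k x 2")
    M <- x
  } else {
    M <- matrix(rep_len(x, k), k, 2)
  }
  dimnames(M) <- list(traits, .SEXES)
  M
}

#' Single-trait truth from standardized variance components
#'
#' @param a2,c2,e2 Standardized additive genetic, shared environmental and
#'   unique environmental shares; must sum to 1 (within 1e-6).
#' @param trait Trait name.
#' @param total_var Total phenotypic variance used to scale the shares.
#' @param mean,age_slope Per-sex intercept and age slope (recycled).
#' @param lognormal Logical; generate on the log scale and exponentiate.
#' @return An \code{\link{ace_truth}} with one trait.
#' @export
univariate_truth <- function(a2, c2, e2 = 1 - a2 - c2, trait = "trait",
                             total_var = 1, mean = 0, age_slope = 0,
                             lognormal = FALSE) {
  s <- a2 + c2 + e2
  if (abs(s - 1) > 1e-6) stop("a2 + c2 + e2 must sum to 1")
  if (min(a2, c2, e2) < 0) stop("variance shares must be non-negative")
  ace_truth(A = a2 * total_var, C = c2 * total_var, E = e2 * total_var,
            traits = trait, means = mean, age_slopes = age_slope,
            lognormal = if (lognormal) trait else character())
}

#' Stacked two-wave truth for longitudinal analyses
#'
#' Builds a bivariate \code{\link{ace_truth}} in which the same trait
#' measured at two waves forms a correlated pair, so cross-wave genetic and
#' environmental correlations are part of the generating model.
#'
#' @param trait Base trait name (shared by both waves).
#' @param a2,c2,e2 Length-2 standardized components at wave 1 and wave 2.
#' @param r_a,r_c,r_e Cross-wave correlations of the A, C and E influences.
#' @param waves Length-2 wave labels.
#' @param total_var Length-2 total phenotypic variances.
#' @param means,age_slopes Length-2 per-wave values (recycled over sexes).
#' @return An \code{\link{ace_truth}} with two wave-tagged traits.
#' @export
crosswave_truth <- function(trait, a2, c2, e2, r_a, r_c = 1, r_e,
                            waves = c("intake", "followup"),
                            total_var = c(1, 1), means = c(0, 0),
                            age_slopes = c(0, 0)) {
  stopifnot(length(a2) == 2, length(c2) == 2, length(e2) == 2,
            length(waves) == 2)
  if (max(abs(a2 + c2 + e2 - 1)) > 1e-6) {
    stop("a2 + c2 + e2 must sum to 1 at each wave")
  }
  comp <- function(sh, r) {
    v <- sh * total_var
    M <- diag(sqrt(v)) %*% matrix(c(1, r, r, 1), 2) %*% diag(sqrt(v))
    .sym(M)
  }
  ace_truth(A = comp(a2, r_a), C = comp(c2, r_c), E = comp(e2, r_e),
            traits = c(trait, trait),
            means = matrix(rep(means, 2), 2, 2),
            age_slopes = matrix(rep(age_slopes, 2), 2, 2),
            trait_wave = waves)
}

#' Model-implied covariance of a stacked twin-pair vector
#'
#' Returns the 2k x 2k covariance of the vector (twin 1 traits, twin 2
#' traits): within-twin blocks A + C + E, and cross-twin blocks A + C for MZ
#' pairs or 0.5 A + C for DZ pairs.
#'
#' @param truth An \code{\link{ace_truth}}.
#' @param zygosity \code{"MZ"} or \code{"DZ"}.
#' @return A symmetric positive-semidefinite matrix.
#' @examples
#' tr <- univariate_truth(0.6, 0.2, 0.2)
#' implied_pair_covariance(tr, "MZ")[1, 2]  # 0.8
#' implied_pair_covariance(tr, "DZ")[1, 2]  # 0.5
#' @export
implied_pair_covariance <- function(truth, zygosity = c("MZ", "DZ")) {
  stopifnot(inherits(truth, "ace_truth"))
  zygosity <- match.arg(zygosity)
  P <- truth$A + truth$C + truth$E
  cross <- if (zygosity == "MZ") truth$A + truth$C else 0.5 * truth$A + truth$C
  S <- rbind(cbind(P, cross), cbind(cross, P))
  k <- length(truth$traits)
  lab <- c(paste0(truth$traits, ".1"), paste0(truth$traits, ".2"))
  dimnames(S) <- list(lab, lab)
  .sym(S)
}

#' @export
print.ace_truth <- function(x, ...) {
  k <- length(x$traits)
  cat(sprintf("Generative ACE truth: %d trait(s)\n", k))
  P <- diag(x$A + x$C + x$E)
  comp <- rbind(a2 = diag(x$A) / P, c2 = diag(x$C) / P, e2 = diag(x$E) / P)
  colnames(comp) <- if (is.null(x$trait_wave)) x$traits else
    paste0(x$traits, "@", x$trait_wave)
  print(round(comp, 3))
  if (length(x$lognormal)) cat("log-normal traits:",
                               paste(x$lognormal, collapse = ", "), "\n")
  invisible(x)
}
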