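#' Simulate a twin cohort with the exact covariance the twin model assumes
#'
#' For every complete pair, a stacked trait vector is drawn from a zero-mean
#' multivariate normal with \code{\link{implied_pair_covariance}}; per-sex
#' means and linear age effects are then added, and log-normal traits are
#' exponentiated. Ages are drawn uniformly within the wave's stated range and
#' shared by co-twins (twins are assessed at the same visit). When the truth
#' carries wave tags, one joint vector per pair covers all waves so that
#' cross-wave correlations are generated; pairs beyond a later wave's pair
#' count simply do not attend that wave. Untagged truths are redrawn
#' independently at each wave.
#'
#' @param design A \code{\link{twin_design}}.
#' @param truth An \code{\link{ace_truth}}.
#' @param seed Integer seed; required, so that identical calls give
#'   byte-identical cohorts.
#' @param missing Missing-completely-at-random rate per trait: a scalar or a
#'   named vector over traits. Default 0 (off).
#' @return A data frame with columns \code{family_id}, \code{twin_index},
#'   \code{zygosity}, \code{sex}, \code{wave}, \code{age} and one column per
#'   trait; one row per individual per attended wave.
#' @examples
#' tr <- univariate_truth(0.6, 0.2, 0.2, trait = "height", total_var = 49,
#'                        mean = 149)
#' coh <- simulate_twins(pair_design(10, 5), tr, seed = 1)
#' nrow(coh)  # 2 * 15 rows
#' @export
simulate_twins <- function(design, truth, seed, missing = 0) {
  stopifnot(inherits(design, "twin_design"), inherits(truth, "ace_truth"))
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  set.seed(as.integer(seed))

  k <- length(truth$traits)
  base_traits <- unique(truth$traits)
  tagged <- !is.null(truth$trait_wave)
  if (tagged && !all(truth$trait_wave %in% design$labels)) {
    stop("truth wave tags must match the design's wave labels")
  }
  miss <- if (length(missing) == 1 && is.null(names(missing))) {
    stats::setNames(rep(missing, length(base_traits)), base_traits)
  } else {
    m <- stats::setNames(rep(0, length(base_traits)), base_traits)
    m[names(missing)] <- missing
    m
  }

  cells <- expand.grid(sex = .SEXES, zygosity = .ZYGOSITIES,
                       stringsAsFactors = FALSE)[, 2:1]
  blocks <- list()
  for (ci in seq_len(nrow(cells))) {
    zyg <- cells$zygosity[ci]; sex <- cells$sex[ci]
    cell <- paste0(zyg, "_", sex)
    counts <- vapply(design$waves, function(w) w$pair_counts[[cell]], 0L)
    n_cell <- max(counts)
    if (n_cell == 0) next
    fam <- sprintf("%s_%s_%04d", zyg, sex, seq_len(n_cell))
    if (tagged) Zall <- .rmvn(n_cell, implied_pair_covariance(truth, zyg))
    for (wi in seq_along(design$waves)) {
      w <- design$waves[[wi]]
      n_w <- counts[wi]
      idx <- if (tagged) which(truth$trait_wave == w$label) else seq_len(k)
      if (n_w == 0 || !length(idx)) next
      Zw <- if (tagged) {
        Zall[seq_len(n_w), c(idx, k + idx), drop = FALSE]
      } else {
        .rmvn(n_w, implied_pair_covariance(truth, zyg))
      }
      kw <- length(idx)
      tnames <- truth$traits[idx]
      a <- w$age[[sex]]
      age <- pmin(pmax(stats::runif(n_w, a["min"], a["max"]), a["min"]),
                  a["max"])
      for (tw in 1:2) {
        V <- Zw[, (tw - 1) * kw + seq_len(kw), drop = FALSE]
        V <- sweep(V, 2, truth$means[idx, sex], "+") +
          outer(age, truth$age_slopes[idx, sex])
        isln <- tnames %in% truth$lognormal
        if (any(isln)) V[, isln] <- exp(V[, isln, drop = FALSE])
        full <- matrix(NA_real_, n_w, length(base_traits),
                       dimnames = list(NULL, base_traits))
        full[, tnames] <- V
        for (bt in base_traits) {
          if (miss[[bt]] > 0) {
            drop_i <- stats::runif(n_w) < miss[[bt]]
            full[drop_i, bt] <- NA_real_
          }
        }
        blocks[[length(blocks) + 1]] <- data.frame(
          family_id = fam[seq_len(n_w)], twin_index = tw, zygosity = zyg,
          sex = sex, wave = w$label, age = age, full,
          stringsAsFactors = FALSE, check.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Write / read a cohort table as CSV
#'
#' Plain UTF-8 CSV with "." decimal separator and empty cells for missing
#' values, so that identical cohorts serialize byte-identically.
#'
#' @param table Cohort data frame from \code{\link{simulate_twins}}.
#' @param path File path.
#' @return \code{write_cohort} returns \code{path} invisibly;
#'   \code{read_cohort} returns the data frame.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  out$family_id <- as.character(out$family_id)
  out
}
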