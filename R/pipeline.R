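#' Configure an end-to-end twin study run
#'
#' @param truth Generating \code{\link{ace_truth}} (a single truth applied
#'   to every stratum; per-sex means and slopes live inside the truth).
#' @param design A \code{\link{twin_design}}; default the built-in MTFS
#'   design.
#' @param seed Integer seed (required for reproducibility).
#' @param sexes Sexes to analyze.
#' @param models Bivariate model policy; default AE first, ACE
#'   confirmation.
#' @param ci Compute profile intervals for the univariate components.
#' @param n_factors Number of factors for the phenotypic factor analysis.
#' @param out_dir Output directory for the report bundle.
#' @return An object of class \code{"study_config"}.
#' @export
study_config <- function(truth, design = mtfs_design(), seed,
                         sexes = c("male", "female"),
                         models = c("AE", "ACE"), ci = TRUE, n_factors = 3,
                         out_dir = tempfile("twinstudy")) {
  stopifnot(inherits(truth, "ace_truth"), inherits(design, "twin_design"))
  if (missing(seed)) stop("'seed' is required")
  sexes <- match.arg(sexes, .SEXES, several.ok = TRUE)
  structure(list(truth = truth, design = design, seed = as.integer(seed),
                 sexes = sexes, models = models, ci = ci,
                 n_factors = n_factors, out_dir = out_dir),
            class = "study_config")
}

#' Run the full study workflow
#'
#' Simulate -> preprocess (log transformation of the truth's log-normal
#' traits, then per-sex per-wave age residualization) -> per-stratum
#' univariate ACE table with AE comparisons -> pairwise genetic-correlation
#' matrices -> cross-wave table (when the truth is wave-tagged) -> factor
#' analysis. Emits a report bundle of plain CSV files plus a JSON manifest
#' and a full-precision JSON sidecar; reported CSV numbers are pinned to
#' two decimals (components and correlations) so identical config and seed
#' give byte-identical bundles. Failures of independent strata are recorded
#' in the manifest and never abort the remaining strata.
#'
#' @param config A \code{\link{study_config}}.
#' @return Invisibly, a list ("bundle") with the univariate table, the
#'   correlation matrices, factor solutions, cross-wave table, manifest and
#'   output paths.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- config$truth
  tagged <- !is.null(truth$trait_wave)
  base_traits <- unique(truth$traits)
  manifest <- list(seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("twinmorph")),
                   strata = list())
  note <- function(key, status, msg = NULL) {
    manifest$strata[[key]] <<- list(status = status, message = msg)
  }

  cohort <- simulate_twins(config$design, truth, seed = config$seed)
  if (length(truth$lognormal)) {
    cohort <- log_transform(cohort, unique(truth$lognormal))
  }
  adjusted <- residualize_age(cohort, base_traits)

  table1 <- descriptive_stats(cohort)
  waves <- config$design$labels
  univ <- list(); rA_paths <- character(); loadings <- list()
  gcors <- list()
  for (w in waves) {
    wave_traits <- if (tagged) {
      unique(truth$traits[truth$trait_wave == w])
    } else base_traits
    if (!length(wave_traits)) next
    for (sx in config$sexes) {
      key <- paste(sx, w, sep = "/")
      res <- tryCatch({
        for (tr in wave_traits) {
          prs <- twin_pairs(adjusted, tr, sex = sx, wave = w)
          ace <- suppressWarnings(twin_ace(prs, "ACE"))
          ae <- suppressWarnings(twin_ace(prs, "AE"))
          cmp <- twin_lrt(ae, ace)
          ci <- if (config$ci) confint(ace) else NULL
          univ[[length(univ) + 1]] <- data.frame(
            trait = tr, sex = sx, wave = w,
            a2 = ace$components["a2"], c2 = ace$components["c2"],
            e2 = ace$components["e2"],
            a2_lo = if (is.null(ci)) NA else ci["a2", "lower"],
            a2_hi = if (is.null(ci)) NA else ci["a2", "upper"],
            c2_lo = if (is.null(ci)) NA else ci["c2", "lower"],
            c2_hi = if (is.null(ci)) NA else ci["c2", "upper"],
            e2_lo = if (is.null(ci)) NA else ci["e2", "lower"],
            e2_hi = if (is.null(ci)) NA else ci["e2", "upper"],
            minus2LL = ace$minus2LL, converged = ace$converged,
            p_c2 = cmp$p, stringsAsFactors = FALSE)
        }
        if (length(wave_traits) >= 2) {
          gc <- genetic_correlation_matrix(adjusted, wave_traits, sex = sx,
                                           wave = w, models = config$models)
          gcors[[key]] <- gc
        }
        if (length(wave_traits) > config$n_factors) {
          rows <- adjusted$sex == sx & adjusted$wave == w
          R <- stats::cor(adjusted[rows, wave_traits, drop = FALSE],
                          use = "pairwise.complete.obs")
          loadings[[key]] <- principal_factor(R, config$n_factors)
        }
        "done"
      }, error = function(e) e)
      if (inherits(res, "error")) {
        note(key, "failed", conditionMessage(res))
      } else note(key, "done")
    }
  }
  univ_tab <- if (length(univ)) do.call(rbind, univ) else NULL

  crosswave <- NULL
  if (length(waves) >= 2) {
    cw_traits <- if (tagged) {
      intersect(unique(truth$traits[truth$trait_wave == waves[1]]),
                unique(truth$traits[truth$trait_wave == waves[2]]))
    } else base_traits
    cw <- list()
    for (tr in cw_traits) {
      for (sx in config$sexes) {
        key <- paste("crosswave", tr, sx, sep = "/")
        res <- tryCatch({
          x <- cross_wave_correlations(adjusted, tr, sex = sx,
                                       waves = waves[1:2])
          cw[[length(cw) + 1]] <- data.frame(
            trait = tr, sex = sx, r = x$r, r_A = x$r_A, r_E = x$r_E,
            stringsAsFactors = FALSE)
          "done"
        }, error = function(e) e)
        if (inherits(res, "error")) {
          note(key, "failed", conditionMessage(res))
        } else note(key, "done")
      }
    }
    crosswave <- if (length(cw)) do.call(rbind, cw) else NULL
  }

  # ---- write the bundle (two-decimal CSVs + full-precision sidecar) ----
  p <- function(f) file.path(config$out_dir, f)
  fmt <- function(df, cols) {
    for (cc in intersect(cols, names(df))) {
      df[[cc]] <- sprintf("%.2f", as.numeric(df[[cc]]))
    }
    df
  }
  utils::write.csv(fmt(table1, c("mean", "sd")), p("table1_descriptives.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(univ_tab)) {
    utils::write.csv(fmt(univ_tab, c("a2", "c2", "e2", "a2_lo", "a2_hi",
                                     "c2_lo", "c2_hi", "e2_lo", "e2_hi")),
                     p("table2_components.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  for (w in waves) {
    keys <- grep(paste0("/", w, "$"), names(gcors), value = TRUE)
    if (!length(keys)) next
    # males upper triangle, females lower triangle, as in the figure layout
    gm <- gcors[[paste("male", w, sep = "/")]]
    gf <- gcors[[paste("female", w, sep = "/")]]
    src <- if (!is.null(gm)) gm else gf
    M <- src$r_A_AE
    if (!is.null(gm) && !is.null(gf)) {
      M[lower.tri(M)] <- gf$r_A_AE[lower.tri(M)]
      M[upper.tri(M)] <- gm$r_A_AE[upper.tri(M)]
    }
    out <- data.frame(trait = rownames(M),
                      apply(M, 2, function(x) sprintf("%.2f", x)),
                      check.names = FALSE)
    utils::write.csv(out, p(sprintf("fig_rA_matrix_%s.csv", w)),
                     row.names = FALSE, quote = FALSE)
    rA_paths <- c(rA_paths, sprintf("fig_rA_matrix_%s.csv", w))
  }
  if (!is.null(crosswave)) {
    utils::write.csv(fmt(crosswave, c("r", "r_A", "r_E")),
                     p("table3_crosswave.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  for (key in names(loadings)) {
    L <- loadings[[key]]
    out <- data.frame(trait = rownames(L$loadings),
                      apply(L$loadings, 2, function(x) sprintf("%.2f", x)),
                      communality = sprintf("%.2f", L$communalities),
                      check.names = FALSE)
    utils::write.csv(out, p(sprintf("loadings_%s.csv",
                                    gsub("/", "_", key))),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  sidecar <- list(univariate = univ_tab, crosswave = crosswave)
  jsonlite::write_json(sidecar, p("results.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")

  bundle <- list(cohort = cohort, adjusted = adjusted,
                 descriptives = table1, univariate = univ_tab,
                 correlations = gcors, crosswave = crosswave,
                 loadings = loadings, manifest = manifest,
                 out_dir = config$out_dir)
  class(bundle) <- "study_bundle"
  invisible(bundle)
}

#' Count traits with significant shared-environmental variance
#'
#' Compares the ACE-vs-AE likelihood-ratio p-values collected by
#' \code{\link{run_study}} against the conventional 0.05 level and the
#' Bonferroni-corrected level alpha/m.
#'
#' @param bundle A bundle from \code{\link{run_study}} (or any data frame
#'   with a \code{p_c2} column).
#' @param alpha Family-wise level.
#' @param m Number of tests; default the number of fits in the bundle.
#' @return List with the two counts, the thresholds and m.
#' @export
significance_summary <- function(bundle, alpha = 0.05, m = NULL) {
  tab <- if (is.data.frame(bundle)) bundle else bundle$univariate
  if (is.null(tab) || !nrow(tab) || !"p_c2" %in% names(tab)) {
    warning("no likelihood-ratio tests in the bundle; empty summary")
    return(list(n_tests = 0L, sig_at_alpha = 0L, sig_at_bonferroni = 0L,
                alpha = alpha, bonferroni = NA_real_))
  }
  if (is.null(m)) m <- nrow(tab)
  thr <- bonferroni_threshold(alpha, m)
  list(n_tests = nrow(tab),
       sig_at_alpha = sum(tab$p_c2 < alpha, na.rm = TRUE),
       sig_at_bonferroni = sum(tab$p_c2 < thr, na.rm = TRUE),
       alpha = alpha, bonferroni = thr)
}
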