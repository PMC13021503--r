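# Published Minnesota Twin Family Study reference estimates used as
# generating truths for parameter-recovery studies. Values are the printed
# point estimates of the anthropometric twin analyses of that cohort:
# standardized variance components per trait/sex/wave, descriptive means and
# SDs, and cross-wave (intake -> follow-up) trait/genetic/environmental
# correlations.

#' Reference standardized variance components
#'
#' Published univariate ACE estimates (a2, c2, e2) for MTFS anthropometric
#' traits by sex and wave, usable as generating truths via
#' \code{\link{reference_truth}}. The intake wave carries all 16 traits;
#' for follow-up a subset relevant to longitudinal analyses is included.
#'
#' @return Data frame with columns trait, sex, wave, a2, c2, e2.
#' @export
mtfs_components <- function() {
  i <- function(trait, ma, mc, me, fa, fc, fe, wave = "intake") {
    data.frame(trait = trait, sex = c("male", "female"), wave = wave,
               a2 = c(ma, fa), c2 = c(mc, fc), e2 = c(me, fe),
               stringsAsFactors = FALSE)
  }
  rbind(
    i("height",              0.78, 0.15, 0.07, 0.71, 0.22, 0.07),
    i("sitting_height",      0.75, 0.11, 0.14, 0.67, 0.23, 0.10),
    i("knee_height",         0.81, 0.11, 0.07, 0.73, 0.17, 0.10),
    i("buttock_knee_length", 0.39, 0.44, 0.17, 0.73, 0.14, 0.13),
    i("foot_length_left",    0.82, 0.08, 0.09, 0.66, 0.23, 0.11),
    i("foot_length_right",   0.83, 0.09, 0.08, 0.64, 0.23, 0.13),
    i("head_circumference",  0.49, 0.35, 0.17, 0.84, 0.01, 0.15),
    i("head_breadth",        0.73, 0.08, 0.20, 0.73, 0.14, 0.13),
    i("head_length_1",       0.58, 0.19, 0.24, 0.67, 0.11, 0.23),
    i("head_length_2",       0.53, 0.26, 0.21, 0.48, 0.34, 0.18),
    i("face_height",         0.30, 0.37, 0.34, 0.41, 0.17, 0.42),
    i("weight",              0.79, 0.12, 0.09, 0.78, 0.14, 0.08),
    i("bmi",                 0.79, 0.12, 0.09, 0.82, 0.10, 0.08),
    i("arm_circumference",   0.76, 0.11, 0.12, 0.83, 0.07, 0.10),
    i("waist_relaxed",       0.55, 0.30, 0.15, 0.65, 0.19, 0.15),
    i("waist_sucking",       0.68, 0.17, 0.15, 0.68, 0.18, 0.14),
    i("height",           0.65, 0.24, 0.11, 0.78, 0.17, 0.06, "followup"),
    i("weight",           0.71, 0.19, 0.10, 0.71, 0.18, 0.11, "followup"),
    i("bmi",              0.77, 0.12, 0.11, 0.62, 0.26, 0.12, "followup"),
    i("head_length_2",    0.37, 0.43, 0.20, 0.54, 0.12, 0.34, "followup"),
    i("shoulder_breadth", 0.27, 0.55, 0.19, 0.23, 0.63, 0.14, "followup"))
}

#' Reference descriptive statistics
#'
#' Published means and SDs for a subset of MTFS anthropometric traits by
#' sex and wave, used to put generating truths on realistic measurement
#' scales.
#'
#' @return Data frame with columns trait, sex, wave, mean, sd.
#' @export
mtfs_descriptives <- function() {
  d <- function(trait, wave, mm, msd, fm, fsd) {
    data.frame(trait = trait, sex = c("male", "female"), wave = wave,
               mean = c(mm, fm), sd = c(msd, fsd), stringsAsFactors = FALSE)
  }
  rbind(
    d("height", "intake", 149, 7.02, 151, 7.31),
    d("weight", "intake", 41.3, 9.53, 44.5, 11.26),
    d("bmi",    "intake", 18.4, 3.22, 19.4, 3.73),
    d("height", "followup", 170, 7.85, 166, 6.4),
    d("weight", "followup", 61.7, 13.03, 65.2, 14.73),
    d("bmi",    "followup", 21.2, 3.58, 23.7, 4.91))
}

#' Reference cross-wave correlations
#'
#' Published intake-to-follow-up trait correlations together with the
#' additive genetic and unique environmental cross-wave correlations for a
#' subset of traits.
#'
#' @return Data frame with columns trait, sex, r, r_A, r_E.
#' @export
mtfs_crosswave <- function() {
  rbind(
    data.frame(trait = "height", sex = "male", r = 0.87, r_A = 0.90,
               r_E = 0.56, stringsAsFactors = FALSE),
    data.frame(trait = "weight", sex = "male", r = 0.91, r_A = 0.94,
               r_E = 0.64),
    data.frame(trait = "bmi", sex = "male", r = 0.90, r_A = 0.95,
               r_E = 0.53),
    data.frame(trait = "height", sex = "female", r = 0.71, r_A = 0.73,
               r_E = 0.49),
    data.frame(trait = "weight", sex = "female", r = 0.78, r_A = 0.80,
               r_E = 0.52),
    data.frame(trait = "head_length_2", sex = "female", r = 0.34,
               r_A = 0.40, r_E = 0.23))
}

#' Generating truth from the reference estimates
#'
#' Builds a univariate \code{\link{ace_truth}} whose standardized
#' components equal the published estimates for one trait/sex/wave
#' (renormalized to sum exactly to 1, since printed values are rounded to
#' two decimals). When the descriptives table carries the trait, the truth
#' is placed on the measurement scale (published mean and SD); otherwise it
#' is standardized.
#'
#' @param trait,sex,wave Row selector for \code{\link{mtfs_components}}.
#' @return An \code{\link{ace_truth}} with one trait.
#' @export
reference_truth <- function(trait, sex, wave = "intake") {
  comp <- mtfs_components()
  row <- comp[comp$trait == trait & comp$sex == sex & comp$wave == wave, ]
  if (nrow(row) != 1) stop("no reference components for this trait/sex/wave")
  sh <- c(row$a2, row$c2, row$e2)
  sh <- sh / sum(sh)
  de <- mtfs_descriptives()
  drow <- de[de$trait == trait & de$sex == sex & de$wave == wave, ]
  tv <- if (nrow(drow) == 1) drow$sd^2 else 1
  mn <- if (nrow(drow) == 1) drow$mean else 0
  univariate_truth(sh[1], sh[2], sh[3], trait = trait, total_var = tv,
                   mean = mn)
}

#' Cross-wave generating truth from the reference estimates
#'
#' Combines the per-wave variance components with the published cross-wave
#' genetic and environmental correlations into a stacked two-wave
#' \code{\link{crosswave_truth}}. The shared-environmental cross-wave
#' correlation is not published; it defaults to 1 (shared environment
#' treated as stable across adolescence), which reproduces the published
#' phenotypic cross-wave correlations well.
#'
#' @param trait,sex Row selectors.
#' @param r_c Assumed shared-environmental cross-wave correlation.
#' @return An \code{\link{ace_truth}} with two wave-tagged traits.
#' @export
reference_crosswave_truth <- function(trait, sex, r_c = 1) {
  comp <- mtfs_components()
  cw <- mtfs_crosswave()
  g1 <- comp[comp$trait == trait & comp$sex == sex & comp$wave == "intake", ]
  g2 <- comp[comp$trait == trait & comp$sex == sex & comp$wave == "followup", ]
  rr <- cw[cw$trait == trait & cw$sex == sex, ]
  if (nrow(g1) != 1 || nrow(g2) != 1 || nrow(rr) != 1) {
    stop("trait not available at both waves in the reference tables")
  }
  norm <- function(g) c(g$a2, g$c2, g$e2) / sum(c(g$a2, g$c2, g$e2))
  s1 <- norm(g1); s2 <- norm(g2)
  crosswave_truth(trait, a2 = c(s1[1], s2[1]), c2 = c(s1[2], s2[2]),
                  e2 = c(s1[3], s2[3]), r_a = rr$r_A, r_c = r_c,
                  r_e = rr$r_E)
}
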