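#' Describe one assessment wave of a twin cohort
#'
#' A wave bundles the complete-pair counts of each zygosity-by-sex cell with
#' the per-sex age distribution at the time of assessment. Ages are later
#' drawn uniformly within \code{[min, max]}; the mean and SD document the
#' target population and must be consistent with the range.
#'
#' @param label Character wave label, e.g. \code{"intake"}.
#' @param pair_counts Named non-negative integer vector with elements
#'   \code{MZ_male}, \code{MZ_female}, \code{DZ_male}, \code{DZ_female}:
#'   numbers of complete twin pairs assessed at this wave.
#' @param age_male,age_female Named numeric vectors \code{c(mean, sd, min,
#'   max)} giving the age distribution (years) for each sex.
#' @return An object of class \code{"cohort_wave"}.
#' @seealso \code{\link{twin_design}}, \code{\link{mtfs_design}}
#' @export
cohort_wave <- function(label, pair_counts, age_male, age_female = age_male) {
  cells <- c("MZ_male", "MZ_female", "DZ_male", "DZ_female")
  if (!all(cells %in% names(pair_counts))) {
    stop("'pair_counts' must be named with ", paste(cells, collapse = ", "))
  }
  pair_counts <- stats::setNames(as.integer(round(pair_counts[cells])), cells)
  if (any(pair_counts < 0)) stop("pair counts must be non-negative")
  check_age <- function(a, sex) {
    need <- c("mean", "sd", "min", "max")
    if (!all(need %in% names(a))) {
      stop(sprintf("age spec for %s needs mean, sd, min, max", sex))
    }
    a <- a[need]
    if (a["sd"] < 0) stop("age SD must be non-negative")
    if (a["mean"] < a["min"] || a["mean"] > a["max"]) {
      stop("mean age must lie inside the stated range")
    }
    a
  }
  structure(
    list(label = as.character(label), pair_counts = pair_counts,
         age = list(male = check_age(age_male, "male"),
                    female = check_age(age_female, "female"))),
    class = "cohort_wave")
}

#' Define a twin-cohort sampling design
#'
#' @param waves List of \code{\link{cohort_wave}} objects, in assessment
#'   order. Pairs attending a later wave are taken to be a subset of those
#'   attending earlier waves (longitudinal attrition), so per-cell counts
#'   should be non-increasing across waves.
#' @return An object of class \code{"twin_design"}.
#' @examples
#' d <- mtfs_design()
#' sum(d$waves[[1]]$pair_counts) * 2  # individuals at intake
#' @export
twin_design <- function(waves) {
  if (inherits(waves, "cohort_wave")) waves <- list(waves)
  if (!length(waves) || !all(vapply(waves, inherits, TRUE, "cohort_wave"))) {
    stop("'waves' must be a list of cohort_wave objects")
  }
  labels <- vapply(waves, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("wave labels must be unique")
  total <- Reduce(`+`, lapply(waves, `[[`, "pair_counts"))
  if (all(total == 0)) stop("at least one zygosity-by-sex cell must be > 0")
  structure(list(waves = waves, labels = labels), class = "twin_design")
}

#' Built-in Minnesota Twin Family Study anthropometric design
#'
#' Two assessment waves of same-sex twin pairs. Intake: 252 male MZ, 233
#' female MZ, 124 male DZ and 147 female DZ complete pairs (1512
#' individuals), mean age 11.7 years (range 10.7-12.8). Follow-up: 207/161/
#' 104/93 complete pairs, with males at mean age 14.8 (13.6-16.9) and
#' females at 18.1 (16.6-20.3).
#'
#' @return A \code{\link{twin_design}} with waves \code{"intake"} and
#'   \code{"followup"}.
#' @export
mtfs_design <- function() {
  intake <- cohort_wave(
    "intake",
    pair_counts = c(MZ_male = 252, MZ_female = 233,
                    DZ_male = 124, DZ_female = 147),
    age_male = c(mean = 11.7, sd = 0.39, min = 10.7, max = 12.8),
    age_female = c(mean = 11.7, sd = 0.46, min = 10.7, max = 12.8))
  followup <- cohort_wave(
    "followup",
    pair_counts = c(MZ_male = 207, MZ_female = 161,
                    DZ_male = 104, DZ_female = 93),
    age_male = c(mean = 14.8, sd = 0.49, min = 13.6, max = 16.9),
    age_female = c(mean = 18.1, sd = 0.71, min = 16.6, max = 20.3))
  twin_design(list(intake, followup))
}

#' Quick single-sex design for simulation studies
#'
#' Convenience constructor used throughout the recovery tests: \code{mz} MZ
#' and \code{dz} DZ complete pairs of one sex, identical counts at every
#' requested wave.
#'
#' @param mz,dz Numbers of complete MZ and DZ pairs.
#' @param sex \code{"male"} or \code{"female"}.
#' @param waves Character vector of wave labels (default one wave).
#' @param age Age spec \code{c(mean, sd, min, max)} reused for every wave.
#' @return A \code{\link{twin_design}}.
#' @export
pair_design <- function(mz, dz, sex = "male", waves = "w1",
                        age = c(mean = 12, sd = 0.5, min = 11, max = 13)) {
  sex <- match.arg(sex, .SEXES)
  counts <- c(MZ_male = 0, MZ_female = 0, DZ_male = 0, DZ_female = 0)
  counts[paste0("MZ_", sex)] <- mz
  counts[paste0("DZ_", sex)] <- dz
  twin_design(lapply(waves, function(w) {
    cohort_wave(w, counts, age_male = age, age_female = age)
  }))
}

#' @export
print.twin_design <- function(x, ...) {
  cat("Twin cohort design:", length(x$waves), "wave(s)\n")
  for (w in x$waves) {
    cat(sprintf("  %s: MZm=%d MZf=%d DZm=%d DZf=%d pairs\n", w$label,
                w$pair_counts["MZ_male"], w$pair_counts["MZ_female"],
                w$pair_counts["DZ_male"], w$pair_counts["DZ_female"]))
  }
  invisible(x)
}
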