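#' Body mass index from weight and height
#'
#' BMI is weight in kilograms divided by the square of height in meters.
#'
#' @param weight_kg Weight in kg; strictly positive.
#' @param height_cm Height in cm; strictly positive.
#' @return BMI in kg/m^2 (vectorized).
#' @examples
#' compute_bmi(41.3, 149)  # 18.60
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  ok <- !is.na(weight_kg) & !is.na(height_cm)
  if (any(weight_kg[ok] <= 0) || any(height_cm[ok] <= 0)) {
    stop("weight and height must be strictly positive")
  }
  weight_kg / (height_cm / 100)^2
}

#' Add a BMI column to a cohort table
#'
#' @param table Cohort data frame.
#' @param weight,height Names of the weight (kg) and height (cm) columns.
#' @param name Name of the new column.
#' @return The table with a BMI column appended.
#' @export
add_bmi <- function(table, weight = "weight", height = "height",
                    name = "bmi") {
  if (!all(c(weight, height) %in% names(table))) {
    stop("weight/height columns not found in table")
  }
  table[[name]] <- compute_bmi(table[[weight]], table[[height]])
  table
}

#' Natural-log transform skewed traits
#'
#' Replaces the named trait columns by their natural logarithm. Log
#' transformation precedes age residualization in this pipeline
#' (normalization first, adjustment second); the base is immaterial for
#' correlations and standardized variance components.
#'
#' @param table Cohort data frame.
#' @param traits Character vector of trait columns to transform.
#' @return The transformed table.
#' @export
log_transform <- function(table, traits) {
  miss_col <- setdiff(traits, names(table))
  if (length(miss_col)) stop("traits not in table: ",
                             paste(miss_col, collapse = ", "))
  for (tr in traits) {
    v <- table[[tr]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      stop(sprintf("non-positive value of '%s' in family %s: cannot log",
                   tr, table$family_id[bad[1]]))
    }
    table[[tr]] <- log(v)
  }
  table
}

#' Residualize traits on exact age within sex-by-wave strata
#'
#' Within each (sex, wave) stratum, each trait is replaced by the residuals
#' of an ordinary least-squares regression on an intercept and exact age,
#' mirroring the adjustment used with the measured data. Residuals have mean
#' zero and zero sample covariance with age in every stratum, and the
#' operation is idempotent. Complete cases per trait: rows missing the trait
#' stay missing; rows missing age get the trait set to missing.
#'
#' @param table Cohort data frame with an \code{age} column.
#' @param traits Trait columns to adjust; default all non-identifier
#'   numeric columns.
#' @return The adjusted table.
#' @export
residualize_age <- function(table, traits = NULL) {
  if (is.null(traits)) traits <- setdiff(names(table), .ID_COLS)
  strata <- interaction(table$sex, table$wave, drop = TRUE)
  for (s in levels(strata)) {
    rows <- which(strata == s)
    if (length(rows) < 3) {
      stop(sprintf("stratum %s has fewer than 3 rows; age slope not estimable",
                   s))
    }
    age <- table$age[rows]
    for (tr in traits) {
      y <- table[[tr]][rows]
      use <- !is.na(y) & !is.na(age)
      table[[tr]][rows[!is.na(y) & is.na(age)]] <- NA_real_
      if (sum(use) < 3) next
      fit <- stats::lm.fit(cbind(1, age[use]), y[use])
      table[[tr]][rows[use]] <- fit$residuals
    }
  }
  table
}

#' Descriptive statistics per trait, sex and wave
#'
#' Sample means and SDs (n - 1 denominator) for every trait in every
#' (sex, wave) cell, the analogue of a cohort descriptives table.
#'
#' @param table Cohort data frame.
#' @param traits Columns to summarize; default age plus all trait columns.
#' @return Data frame with columns trait, sex, wave, n, mean, sd. Cells with
#'   a single observation get an NA SD; empty cells are omitted with a
#'   warning.
#' @export
descriptive_stats <- function(table, traits = NULL) {
  if (is.null(traits)) traits <- c("age", setdiff(names(table), .ID_COLS))
  out <- list()
  for (w in unique(table$wave)) {
    for (sx in unique(table$sex)) {
      rows <- table$sex == sx & table$wave == w
      for (tr in traits) {
        v <- table[[tr]][rows]
        v <- v[!is.na(v)]
        if (!length(v)) {
          warning(sprintf("no observations for %s / %s / %s; omitted",
                          tr, sx, w))
          next
        }
        out[[length(out) + 1]] <- data.frame(
          trait = tr, sex = sx, wave = w, n = length(v), mean = mean(v),
          sd = if (length(v) > 1) stats::sd(v) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
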