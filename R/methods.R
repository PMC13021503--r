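# S3 methods for fitted twin models.

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("Twin %s model: %s\n", x$model,
              paste(x$trait, collapse = ", ")))
  cat(sprintf("  pairs: %d MZ, %d DZ\n", x$n_pairs["MZ"], x$n_pairs["DZ"]))
  if (x$model != "SAT") {
    cat("  standardized components:\n")
    print(round(x$components, 4))
  }
  cat(sprintf("  -2 log-likelihood: %.3f  (%d parameters)%s\n",
              x$minus2LL, x$n_params,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Summarize a fitted twin model
#'
#' @param object A \code{\link{twin_ace}} fit.
#' @param ci Compute profile-likelihood intervals for the components.
#' @param level Confidence level for \code{ci}.
#' @param ... Unused.
#' @return An object of class \code{"summary.twin_fit"}.
#' @export
summary.twin_fit <- function(object, ci = FALSE, level = 0.95, ...) {
  out <- object[c("model", "trait", "n_pairs", "minus2LL", "n_params",
                  "converged", "warnings")]
  if (object$model != "SAT") {
    out$components <- object$components
    out$paths <- object$paths
    out$mean <- object$mean
    if (ci) out$ci <- confint(object, level = level)
  }
  class(out) <- "summary.twin_fit"
  out
}

#' @export
print.summary.twin_fit <- function(x, ...) {
  cat(sprintf("Twin %s model for %s\n", x$model,
              paste(x$trait, collapse = ", ")))
  cat(sprintf("Pairs: %d MZ, %d DZ;  -2lnL = %.3f on %d parameters\n",
              x$n_pairs["MZ"], x$n_pairs["DZ"], x$minus2LL, x$n_params))
  if (!is.null(x$components)) {
    tab <- data.frame(estimate = round(x$components, 4))
    if (!is.null(x$ci)) {
      tab$lower <- round(x$ci[rownames(tab), "lower"], 4)
      tab$upper <- round(x$ci[rownames(tab), "upper"], 4)
    }
    print(tab)
  }
  if (!isTRUE(x$converged)) cat("WARNING: optimizer did not converge\n")
  for (w in x$warnings) cat("note:", w, "\n")
  invisible(x)
}

#' @export
coef.twin_fit <- function(object, ...) {
  if (object$model == "SAT") {
    return(unlist(object$moments))
  }
  c(object$components, object$paths, mean = object$mean)
}

#' @export
logLik.twin_fit <- function(object, ...) {
  structure(-object$minus2LL / 2, df = object$n_params,
            nobs = sum(object$n_pairs), class = "logLik")
}

#' Simulate pair data from a fitted twin model
#'
#' Parametric draws with the fitted variance components and group sizes,
#' useful for bootstrap checks.
#'
#' @param object A structured \code{\link{twin_ace}} fit.
#' @param nsim Number of replicate data sets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of \code{\link{twin_pairs}} objects.
#' @export
simulate.twin_fit <- function(object, nsim = 1, seed = 1, ...) {
  if (object$model == "SAT") stop("simulate() needs a structured fit")
  set.seed(as.integer(seed))
  sh <- object$components
  tr <- univariate_truth(sh["a2"], sh["c2"], sh["e2"],
                         total_var = sum(object$paths^2),
                         mean = object$mean, trait = object$trait[1])
  replicate(nsim,
            .simulate_pairs(tr, object$n_pairs["MZ"], object$n_pairs["DZ"]),
            simplify = FALSE)
}

#' @export
plot.twin_fit <- function(x, ci = FALSE, ...) {
  if (x$model == "SAT") stop("plot() needs a structured fit")
  h <- graphics::barplot(x$components, ylim = c(0, 1),
                         ylab = "share of phenotypic variance",
                         main = paste(x$model, "decomposition:",
                                      paste(x$trait, collapse = ", ")), ...)
  if (ci) {
    iv <- confint(x)
    keep <- names(x$components) %in% rownames(iv)
    graphics::arrows(h[keep], iv[, "lower"], h[keep], iv[, "upper"],
                     angle = 90, code = 3, length = 0.06)
  }
  invisible(x)
}
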