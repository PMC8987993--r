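#' @include AllClasses.R
NULL

#' Predicted age difference (PAD)
#'
#' PAD is the difference between brain-predicted and chronological age, in
#' years; positive values indicate an older-appearing brain.
#'
#' @param predicted,chronological numeric vectors of equal length (years).
#' @return numeric vector of uncorrected PAD scores.
#' @examples
#' computePAD(75, 70)
#' @export
computePAD <- function(predicted, chronological) {
  .assert(length(predicted) == length(chronological),
          "predicted and chronological must have equal length")
  as.numeric(predicted) - as.numeric(chronological)
}

#' Fit the linear age-bias correction
#'
#' Uncorrected PAD typically shows a spurious linear dependence on
#' chronological age (regression-to-the-mean of the age prediction). The
#' correction is the OLS regression of PAD on age fitted on a designated
#' reference sample; subtracting the fitted line removes the trend.
#'
#' @param pad uncorrected PAD scores (years).
#' @param ages chronological ages (years), non-degenerate, `n >= 3`.
#' @param reference label recording which sample the fit used.
#' @return a [BiasCorrection-class].
#' @examples
#' fitBiasCorrection(c(-1, 0, 2, 1), c(20, 40, 60, 80))
#' @export
fitBiasCorrection <- function(pad, ages, reference = "reference") {
  .assert(length(pad) == length(ages), "pad and ages must have equal length")
  .assert(length(pad) >= 3, "need at least 3 observations")
  .checkFinite(pad, "pad"); .checkFinite(ages, "ages")
  .assert(stats::sd(ages) > 0, "ages have zero variance; fit is undefined")
  fit <- stats::lm.fit(cbind(1, ages), pad)
  new("BiasCorrection", slope = unname(fit$coefficients[2]),
      intercept = unname(fit$coefficients[1]),
      reference = as.character(reference))
}

#' Apply a fitted age-bias correction
#'
#' Corrected PAD is `pad - (slope * age + intercept)`. On the reference
#' sample itself the corrected scores are exactly uncorrelated with age
#' (OLS residual orthogonality).
#'
#' @param pad uncorrected PAD scores.
#' @param ages chronological ages.
#' @param correction a [BiasCorrection-class].
#' @return corrected PAD scores (years).
#' @export
applyBiasCorrection <- function(pad, ages, correction) {
  .assert(is(correction, "BiasCorrection"),
          "correction must be a BiasCorrection")
  .assert(length(pad) == length(ages), "pad and ages must have equal length")
  pad - (correction@slope * ages + correction@intercept)
}

setMethod("show", "BiasCorrection", function(object) {
  cat(sprintf("BiasCorrection (ref: %s): corrected = pad - (%.4f * age + %.4f)\n",
              object@reference, object@slope, object@intercept))
  invisible(NULL)
})
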