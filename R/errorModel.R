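#' Measurement-error variance at a measured intensity
#'
#' Evaluates the error model at intensity `x`:
#' `variance = technicalSD^2 + (biologicalCV * x)^2`. The technical term is
#' a floor, so the variance never vanishes; the biological term makes it
#' non-decreasing in the signal. The CV is applied to the measured level.
#'
#' @param model an [ErrorModel-class].
#' @param x numeric vector of non-negative intensities.
#' @return Numeric vector of variances (intensity units squared).
#' @examples
#' varianceOf(ErrorModel(300, 0.08), c(0, 1000))  # 90000, 96400
#' @export
setMethod("varianceOf", "ErrorModel", function(model, x) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("intensities must be finite and >= 0")
  model@technicalSD^2 + (model@biologicalCV * x)^2
})

#' Difference between two conditions with its error variance
#'
#' Computes `X(t | condA) - X(t | condB)` for one protein together with the
#' variance of that difference. Measurement errors of the two conditions
#' are treated as independent, so their variances add.
#'
#' @param ds a [PerturbationExperiment-class].
#' @param model an [ErrorModel-class].
#' @param protein protein id (row of `ds`).
#' @param condA,condB [Condition-class] objects.
#' @param time time in minutes; must be measured for both conditions.
#' @return Named list with elements `difference` and `variance`.
#' @examples
#' ds <- simulateDataset(sampleGroundTruth(seed = 1), noise = FALSE)
#' deltaWithVariance(ds, ErrorModel(), proteins(ds)[1],
#'                   Condition(stimuli = stimulusIds(ds)[1]), Condition(), 30)
#' @export
deltaWithVariance <- function(ds, model, protein, condA, condB, time) {
  xa <- levelAt(ds, protein, condA@stimuli, condA@inhibitors, time)
  xb <- levelAt(ds, protein, condB@stimuli, condB@inhibitors, time)
  list(difference = xa - xb,
       variance = varianceOf(model, xa) + varianceOf(model, xb))
}
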