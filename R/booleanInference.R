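#' Significance of stimulus and inhibitor actions
#'
#' `stimulusSignificant` tests whether a stimulus significantly *raises* a
#' protein: it returns 1 iff at some post-baseline time t > 0 the increase
#' over the untreated reference exceeds `k` standard deviations of the
#' difference's measurement error,
#' `X(t|i,0) - X(t|0,0) > k * sqrt(var[X(t|i,0)] + var[X(t|0,0)])`.
#' The test is one-sided: only increases count, and the t = 0 sample is
#' excluded since no stimulus can act at time zero.
#'
#' `inhibitorSignificant` tests, given an acting stimulus, whether an
#' inhibitor significantly *lowers* the protein relative to the
#' stimulus-alone course: 1 iff at some t > 0
#' `X(t|i,0) - X(t|i,j) > k * sqrt(var_delta)`. It must only be called when
#' the stimulus itself is significant; when the stimulus does not act, the
#' inhibitor's effect is not assessed and the table cell stays `[0,0]`.
#'
#' `k` may be a vector; the condition is evaluated independently at each
#' value (useful for sweeps).
#'
#' @param ds a [PerturbationExperiment-class] with single-perturbation
#'   training conditions.
#' @param model an [ErrorModel-class].
#' @param protein,stimulus,inhibitor ids.
#' @param k positive significance multiplier(s).
#' @return Integer 0/1, one per element of `k`.
#' @seealso [stimulusKThreshold()], [buildBooleanTable()]
#' @export
stimulusSignificant <- function(ds, model, protein, stimulus, k) {
  if (any(k <= 0)) stop("'k' must be positive")
  z <- stimulusContrast(asIndex(ds), model, protein, stimulus)
  vapply(k, function(kk) as.integer(any(z$delta > kk * z$sd)), integer(1))
}

#' @rdname stimulusSignificant
#' @export
inhibitorSignificant <- function(ds, model, protein, stimulus, inhibitor, k) {
  if (any(k <= 0)) stop("'k' must be positive")
  idx <- asIndex(ds)
  if (stimulusSignificant(idx, model, protein, stimulus, min(k)) == 0L)
    stop("inhibitor action is only assessed when the stimulus acts ",
         "(stimulus '", stimulus, "' is not significant for '", protein,
         "' at k = ", min(k), ")")
  z <- inhibitorContrast(idx, model, protein, stimulus, inhibitor)
  vapply(k, function(kk) as.integer(any(z$delta > kk * z$sd)), integer(1))
}

# Post-baseline differences and their error SDs for the two tests; idx is
# a fastIndex() of the dataset.
stimulusContrast <- function(idx, model, protein, stimulus) {
  xa <- .course(idx, protein, paste0(stimulus, "|"))
  xr <- .course(idx, protein, "|")
  tpos <- idx$tp > 0
  list(delta = (xa - xr)[tpos],
       sd = sqrt(varianceOf(model, xa) + varianceOf(model, xr))[tpos])
}

inhibitorContrast <- function(idx, model, protein, stimulus, inhibitor) {
  xa <- .course(idx, protein, paste0(stimulus, "|"))
  xj <- .course(idx, protein, paste0(stimulus, "|", inhibitor))
  tpos <- idx$tp > 0
  list(delta = (xa - xj)[tpos],
       sd = sqrt(varianceOf(model, xa) + varianceOf(model, xj))[tpos])
}

#' Analytic k-threshold of a stimulus or inhibitor action
#'
#' The largest significance multiplier still admitting the action: the
#' maximum over post-baseline times of the signed difference divided by the
#' error SD of the difference. An action is significant at `k` exactly when
#' `k < k_max` (strict: at `k = k_max` the action is excluded, reading the
#' threshold as a supremum). A non-positive `k_max` means the action is
#' never significant for any positive `k`.
#'
#' @inheritParams stimulusSignificant
#' @return A single numeric `k_max` (dimensionless).
#' @export
stimulusKThreshold <- function(ds, model, protein, stimulus) {
  z <- stimulusContrast(asIndex(ds), model, protein, stimulus)
  max(z$delta / z$sd)
}

#' @rdname stimulusKThreshold
#' @export
inhibitorKThreshold <- function(ds, model, protein, stimulus, inhibitor) {
  z <- inhibitorContrast(asIndex(ds), model, protein, stimulus, inhibitor)
  max(z$delta / z$sd)
}

#' Build the Boolean stimulus/inhibitor table of one protein
#'
#' Fills the per-protein table cell by cell: `s` per stimulus column from
#' [stimulusSignificant()]; where `s = 1`, `v` per inhibitor row from
#' [inhibitorSignificant()]; where `s = 0` the whole column is `[0,0]` and
#' inhibitors are not assessed.
#'
#' @inheritParams stimulusSignificant
#' @param k a single positive significance multiplier.
#' @return A [BooleanTable-class].
#' @examples
#' ds <- simulateDataset(sampleGroundTruth(seed = 3), noise = FALSE)
#' buildBooleanTable(ds, ErrorModel(), proteins(ds)[1], k = 2.5)
#' @export
buildBooleanTable <- function(ds, model, protein, k) {
  stopifnot(length(k) == 1L, k > 0)
  idx <- asIndex(ds)
  stim <- idx$stim
  inh <- idx$inh
  s <- vapply(stim, function(i)
    stimulusSignificant(idx, model, protein, i, k), integer(1))
  v <- matrix(0L, nrow = length(inh), ncol = length(stim),
              dimnames = list(inh, stim))
  for (i in stim[s == 1L])
    for (j in inh)
      v[j, i] <- inhibitorSignificant(idx, model, protein, i, j, k)
  meds <- stats::setNames(rep(list(character(0)), length(stim)), stim)
  new("BooleanTable", protein = protein, s = s, v = v, mediators = meds)
}

#' All pairwise k-thresholds of a dataset
#'
#' Computes, for every protein, the stimulus threshold of every stimulus
#' and the inhibitor threshold of every (stimulus, inhibitor) pair.
#' Inhibitor thresholds are reported unconditionally (the significance test
#' itself additionally requires the stimulus to act).
#'
#' @inheritParams stimulusSignificant
#' @return Nested list: per protein, `stimulus` (named numeric) and
#'   `inhibitor` (numeric matrix, inhibitors x stimuli).
#' @seealso [writeKThresholds()]
#' @export
kThresholds <- function(ds, model) {
  idx <- asIndex(ds)
  stim <- idx$stim; inh <- idx$inh
  out <- lapply(idx$prot, function(p) {
    sThr <- vapply(stim, function(i)
      stimulusKThreshold(idx, model, p, i), numeric(1))
    vThr <- matrix(NA_real_, length(inh), length(stim),
                   dimnames = list(inh, stim))
    for (i in stim) for (j in inh)
      vThr[j, i] <- inhibitorKThreshold(idx, model, p, i, j)
    list(stimulus = sThr, inhibitor = vThr)
  })
  names(out) <- idx$prot
  out
}

#' Serialize Boolean tables and k-thresholds
#'
#' `writeBooleanTables` writes one CSV per protein (rows = inhibitors,
#' columns = stimuli, cell text `"s,v"`); `writeKThresholds` dumps the
#' [kThresholds()] structure as JSON.
#'
#' @param tables named list of [BooleanTable-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
writeBooleanTables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(tables, function(tb) {
    cells <- matrix(paste(rep(tb@s, each = nrow(tb@v)), tb@v, sep = ","),
                    nrow = nrow(tb@v), dimnames = dimnames(tb@v))
    p <- file.path(dir, paste0(tb@protein, "_table.csv"))
    utils::write.csv(as.data.frame(cells), p)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname writeBooleanTables
#' @param thresholds output of [kThresholds()].
#' @param path output JSON path.
#' @export
writeKThresholds <- function(thresholds, path) {
  out <- lapply(thresholds, function(z)
    list(stimulus = as.list(z$stimulus),
         inhibitor = apply(z$inhibitor, 1L, as.list, simplify = FALSE)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
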