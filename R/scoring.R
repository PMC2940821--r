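#' Normalized error of one prediction
#'
#' The absolute deviation of a prediction from its measurement in units of
#' the measurement-error SD at the measured level:
#' `NE = |pred - meas| / sqrt(variance(meas))`. An NE of 1 means the
#' prediction misses by exactly one SD of the assay error.
#'
#' @param pred,meas numeric vectors of predicted and measured intensities
#'   (recycled to common length); `meas >= 0`.
#' @param model an [ErrorModel-class].
#' @return Numeric vector of NE values (dimensionless, `>= 0`).
#' @export
normalizedError <- function(pred, meas, model) {
  abs(pred - meas) / sqrt(varianceOf(model, meas))
}

#' Normalized squared error of one protein
#'
#' Mean over the protein's predictions of NE squared.
#'
#' @param ne numeric vector of the protein's normalized errors.
#' @return A single NSE value.
#' @export
proteinNSE <- function(ne) {
  if (!length(ne)) stop("NSE of an empty prediction set is undefined")
  mean(ne^2)
}

#' Empirical null p-value of a protein's NSE
#'
#' Builds a resampling null: each of the protein's predictions is replaced
#' by a uniform draw (with replacement) from the pool of that protein's
#' measured values, and the null NSE recomputed, `nDraws` times. The
#' p-value is add-one smoothed,
#' `p = (1 + #\{null NSE <= observed NSE\}) / (nDraws + 1)`, so it is
#' always positive. Seeded and reproducible; the caller's RNG state is
#' untouched.
#'
#' @param predicted,measured numeric vectors over the protein's
#'   predictions.
#' @param pool numeric vector of all measured values of the protein.
#' @param model an [ErrorModel-class].
#' @param nDraws number of null resamples (>= 100).
#' @param seed integer seed.
#' @return p-value in (0, 1].
#' @export
nullPValue <- function(predicted, measured, pool, model, nDraws = 10000L,
                       seed = 1L) {
  if (!length(pool)) stop("empty measurement pool")
  if (nDraws < 100L) stop("'nDraws' must be at least 100")
  obs <- proteinNSE(normalizedError(predicted, measured, model))
  m <- length(measured)
  vm <- varianceOf(model, measured)
  nullNSE <- withSeed(seed, {
    draws <- matrix(sample(pool, nDraws * m, replace = TRUE), nrow = nDraws)
    rowMeans((draws - rep(measured, each = nDraws))^2 /
               rep(vm, each = nDraws))
  })
  (1 + sum(nullNSE <= obs)) / (nDraws + 1)
}

#' Prediction Score from per-protein p-values
#'
#' Combines the per-protein null p-values as the mean of `-log10(p)`
#' (the DREAM convention): larger means more significant predictions.
#'
#' @param pValues numeric vector of p-values in (0, 1].
#' @return A single score.
#' @export
predictionScore <- function(pValues) {
  if (any(pValues <= 0 | pValues > 1)) stop("p-values must be in (0, 1]")
  mean(-log10(pValues))
}

#' Overall Score: Prediction Score penalized per network edge
#'
#' `overall = predictionScore - r * edgeCount`; the cost per link `r`
#' rewards sparse networks (the challenge value is r = 0.0827).
#'
#' @param predScore Prediction Score.
#' @param edgeCount number of edges in the submitted network (>= 0).
#' @param r non-negative cost per edge.
#' @return A single score.
#' @export
overallScore <- function(predScore, edgeCount, r = 0.0827) {
  stopifnot(edgeCount >= 0, r >= 0)
  predScore - r * edgeCount
}

#' Full score report for a set of predictions
#'
#' Joins predictions to measurements by (protein, condition, time),
#' computes per-prediction NEs, per-protein NSEs and null p-values, the
#' Prediction Score and the edge-penalized Overall Score.
#'
#' @param records predictions from [predictBatch()] (needs columns
#'   `protein`, `stimuli`, `inhibitors`, `time_min`, `predicted`).
#' @param measurements data.frame with columns `protein`, `stimuli`,
#'   `inhibitors`, `time_min`, `measured` covering every prediction.
#' @param model an [ErrorModel-class].
#' @param net the submitted [SignalingNetwork-class] (for the edge count).
#' @param r cost per edge (default 0.0827).
#' @param nDraws null resamples per protein (default 10000).
#' @param seed integer seed for the resampling null.
#' @return A [ScoreReport-class].
#' @seealso [writeScoreReport()]
#' @export
scoreReport <- function(records, measurements, model, net, r = 0.0827,
                        nDraws = 10000L, seed = 1L) {
  keyOf <- function(d) paste(d$protein, d$stimuli, d$inhibitors, d$time_min,
                             sep = "|")
  idx <- match(keyOf(records), keyOf(measurements))
  if (anyNA(idx))
    stop("no measurement for prediction(s): ",
         paste(utils::head(keyOf(records)[is.na(idx)], 5L), collapse = ", "))
  df <- records[, c("protein", "stimuli", "inhibitors", "time_min",
                    "predicted")]
  df$measured <- measurements$measured[idx]
  df$ne <- normalizedError(df$predicted, df$measured, model)

  prots <- sort(unique(df$protein))
  nse <- vapply(prots, function(p) proteinNSE(df$ne[df$protein == p]),
                numeric(1))
  pv <- vapply(seq_along(prots), function(ip) {
    p <- prots[ip]
    sel <- df$protein == p
    pool <- measurements$measured[measurements$protein == p]
    nullPValue(df$predicted[sel], df$measured[sel], pool, model,
               nDraws = nDraws, seed = childSeed(seed, ip))
  }, numeric(1))
  names(pv) <- prots
  ps <- predictionScore(pv)
  ec <- edgeCount(net)
  new("ScoreReport", perPredictionNE = df, perProteinNSE = nse,
      pValues = pv, predictionScore = ps,
      overallScore = overallScore(ps, ec, r), r = r,
      edgeCount = as.integer(ec), meanNE = mean(df$ne),
      medianNE = stats::median(df$ne), nullDraws = as.integer(nDraws),
      seed = as.integer(seed))
}

#' Serialize a score report
#'
#' Writes the report as JSON (all scalar and per-protein fields) and,
#' optionally, the flat per-prediction NE table as CSV.
#'
#' @param report a [ScoreReport-class].
#' @param path output JSON path.
#' @param nePath optional CSV path for per-prediction NEs.
#' @return Invisibly, `path`.
#' @export
writeScoreReport <- function(report, path, nePath = NULL) {
  out <- list(
    prediction_score = report@predictionScore,
    overall_score = report@overallScore,
    r = report@r,
    edge_count = report@edgeCount,
    mean_ne = report@meanNE,
    median_ne = report@medianNE,
    null_draws = report@nullDraws,
    seed = report@seed,
    per_protein_nse = as.list(report@perProteinNSE),
    per_protein_p = as.list(report@pValues))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(nePath))
    utils::write.csv(report@perPredictionNE, nePath, row.names = FALSE)
  invisible(path)
}
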