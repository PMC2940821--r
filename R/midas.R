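#' Read a MIDAS-dialect perturbation CSV
#'
#' Parses the CellNOpt-compatible MIDAS dialect: treatment columns
#' `TR:<id>` holding 0/1 (a trailing lowercase `i` in the id marks an
#' inhibitor, e.g. `TR:MEKi`), a `DA:ALL` column with the row's time in
#' minutes, and one `DV:<protein>` column per measured phosphoprotein. One
#' row per (condition, time). Per-protein time columns `DA:<protein>` are
#' accepted instead of `DA:ALL` but must agree within each row. Replicate
#' rows (same condition and time) are averaged per data column.
#'
#' @param path path to the CSV file.
#' @param inhibitorTargets optional named character mapping inhibitor ids to
#'   their target protein nodes; defaults to stripping the trailing `i`.
#' @return A [PerturbationExperiment-class].
#' @seealso [writeMIDAS()]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' makeFixture("tiny", seed = 1, dir = tempdir())
#' ds <- readMIDAS(file.path(tempdir(), "training.csv"))
#' @export
readMIDAS <- function(path, inhibitorTargets = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cn <- colnames(df)
  trCols <- grep("^TR:", cn, value = TRUE)
  daCols <- grep("^DA:", cn, value = TRUE)
  dvCols <- grep("^DV:", cn, value = TRUE)
  if (!length(dvCols)) stop("malformed header: no DV: data columns in ", path)
  if (!length(daCols)) stop("malformed header: no DA: time column in ", path)

  trIds <- sub("^TR:", "", trCols)
  isInh <- grepl("i$", trIds)
  stimCols <- trCols[!isInh]; inhCols <- trCols[isInh]
  stimIds <- trIds[!isInh];   inhIds <- trIds[isInh]

  checkNum <- function(cols) {
    for (cc in cols) {
      v <- suppressWarnings(as.numeric(df[[cc]]))
      bad <- which(is.na(v) & !is.na(df[[cc]]) | is.na(df[[cc]]))
      if (length(bad))
        stop("non-numeric value in column '", cc, "', row ", bad[1L] + 1L,
             " of ", path)
      df[[cc]] <<- v
    }
  }
  checkNum(c(trCols, daCols, dvCols))
  for (cc in trCols)
    if (!all(df[[cc]] %in% c(0, 1)))
      stop("treatment column '", cc, "' must be 0/1 in ", path)

  if ("DA:ALL" %in% daCols) {
    time <- df[["DA:ALL"]]
  } else {
    tm <- as.matrix(df[daCols])
    if (any(apply(tm, 1L, function(r) length(unique(r)) != 1L))) {
      bad <- which(apply(tm, 1L, function(r) length(unique(r)) != 1L))[1L]
      stop("per-protein DA: times disagree in row ", bad + 1L, " of ", path)
    }
    time <- tm[, 1L]
  }

  sampStim <- if (length(stimCols))
    apply(as.matrix(df[stimCols]), 1L, function(r) joinIds(stimIds[r == 1]))
  else rep("", nrow(df))
  sampInh <- if (length(inhCols))
    apply(as.matrix(df[inhCols]), 1L, function(r) joinIds(inhIds[r == 1]))
  else rep("", nrow(df))

  protIds <- sub("^DV:", "", dvCols)
  vals <- t(as.matrix(df[dvCols]))
  rownames(vals) <- protIds

  # average replicates per (condition, time)
  grp <- paste(sampStim, sampInh, time, sep = "|")
  if (anyDuplicated(grp)) {
    keep <- !duplicated(grp)
    agg <- vapply(unique(grp), function(g)
      rowMeans(vals[, grp == g, drop = FALSE]), numeric(nrow(vals)))
    vals <- matrix(agg, nrow = nrow(vals),
                   dimnames = list(protIds, unique(grp)))
    sampStim <- sampStim[keep]; sampInh <- sampInh[keep]; time <- time[keep]
  }

  refKey <- conditionKey(character(0), character(0))
  keys <- paste(sampStim, sampInh, sep = "|")
  if (!any(keys == refKey))
    stop("missing reference condition (all TR: columns 0) in ", path)

  pe <- PerturbationExperiment(vals, stimuli = sampStim, inhibitors = sampInh,
                               time = time, stimulusIds = sort(stimIds),
                               inhibitorIds = sort(inhIds),
                               inhibitorTargets = inhibitorTargets)
  validObject(pe)
  pe
}

#' Write a MIDAS-dialect perturbation CSV
#'
#' Emits the dialect read by [readMIDAS()]: `TR:` columns for the stimulus
#' and inhibitor panels, `DA:ALL`, and `DV:` columns per protein; one row
#' per (condition, time), ordered by condition key then time. Values
#' round-trip through [readMIDAS()] up to float formatting.
#'
#' @param ds a [PerturbationExperiment-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeMIDAS <- function(ds, path) {
  if (!is(ds, "PerturbationExperiment")) stop("'ds' must be a PerturbationExperiment")
  if (nrow(ds) == 0L) stop("dataset has no proteins")
  cd <- colData(ds)
  o <- order(cd$key, cd$time)
  x <- SummarizedExperiment::assay(ds, "intensity")[, o, drop = FALSE]
  cd <- cd[o, ]
  out <- data.frame(row.names = seq_len(nrow(cd)))
  for (s in stimulusIds(ds))
    out[[paste0("TR:", s)]] <-
      as.integer(vapply(cd$stimuli, function(v) s %in% splitIds(v), logical(1)))
  for (i in inhibitorIds(ds))
    out[[paste0("TR:", i)]] <-
      as.integer(vapply(cd$inhibitors, function(v) i %in% splitIds(v), logical(1)))
  out[["DA:ALL"]] <- cd$time
  for (p in rownames(ds)) out[[paste0("DV:", p)]] <- x[p, ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
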