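#' Construct a PerturbationExperiment
#'
#' Assembles the package's central data container from an intensity matrix
#' (proteins x samples) and per-sample treatment annotation.
#'
#' @param intensity numeric matrix, proteins as rows (rownames required),
#'   one column per (condition, time) sample.
#' @param stimuli,inhibitors per-sample treatments: either character vectors
#'   of `+`-joined id strings (`""` for none) or lists of character vectors.
#' @param time per-sample time in minutes.
#' @param stimulusIds,inhibitorIds full treatment panels; defaults to the
#'   ids observed in the annotation.
#' @param inhibitorTargets named character mapping each inhibitor id to the
#'   protein node it blocks; defaults to the id with a trailing `"i"`
#'   stripped (`"MEKi" -> "MEK"`).
#' @return A [PerturbationExperiment-class].
#' @examples
#' m <- rbind(P1 = c(100, 150, 100, 400))
#' pe <- PerturbationExperiment(m,
#'   stimuli = c("", "", "S1", "S1"),
#'   inhibitors = "", time = c(0, 30, 0, 30))
#' levelAt(pe, "P1", "S1", character(0), 30)
#' @export
PerturbationExperiment <- function(intensity, stimuli, inhibitors, time,
                                   stimulusIds = NULL, inhibitorIds = NULL,
                                   inhibitorTargets = NULL) {
  intensity <- as.matrix(intensity)
  n <- ncol(intensity)
  norm <- function(x) {
    if (is.list(x)) vapply(x, joinIds, character(1))
    else vapply(as.character(x), function(s) joinIds(splitIds(s)), character(1),
                USE.NAMES = FALSE)
  }
  stimuli <- rep_len(norm(stimuli), n)
  inhibitors <- rep_len(norm(inhibitors), n)
  time <- rep_len(as.numeric(time), n)
  key <- paste(stimuli, inhibitors, sep = "|")
  if (is.null(stimulusIds))
    stimulusIds <- sort(unique(unlist(lapply(stimuli, splitIds))))
  if (is.null(inhibitorIds))
    inhibitorIds <- sort(unique(unlist(lapply(inhibitors, splitIds))))
  if (is.null(inhibitorTargets)) {
    inhibitorTargets <- sub("i$", "", inhibitorIds)
    names(inhibitorTargets) <- inhibitorIds
  }
  if (length(inhibitorIds) && !all(inhibitorIds %in% names(inhibitorTargets)))
    stop("inhibitorTargets must cover every inhibitor id")
  inhibitorTargets <- inhibitorTargets[inhibitorIds]
  colnames(intensity) <- paste0(key, "@", time)
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    colData = DataFrame(stimuli = stimuli, inhibitors = inhibitors,
                        time = time, key = key,
                        row.names = colnames(intensity)),
    metadata = list(stimulusIds = as.character(stimulusIds),
                    inhibitorIds = as.character(inhibitorIds),
                    inhibitorTargets = inhibitorTargets)
  )
  new("PerturbationExperiment", se)
}

#' Accessors for PerturbLink objects
#'
#' `stimulusIds`, `inhibitorIds`, `inhibitorTargets`, `timePoints` and
#' `proteins` expose the panels of a [PerturbationExperiment-class] (or of
#' a [GroundTruth-class]); `edges`, `edgeCount` and `networkNodes` expose a
#' [SignalingNetwork-class]; `network`, `booleanTables` and `rankedLinks`
#' expose an [InferredModel-class].
#'
#' @param object the object to access.
#' @return The corresponding component (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("stimulusIds", "PerturbationExperiment",
          function(object) metadata(object)$stimulusIds)

#' @rdname accessors
#' @export
setMethod("inhibitorIds", "PerturbationExperiment",
          function(object) metadata(object)$inhibitorIds)

#' @rdname accessors
#' @export
setMethod("inhibitorTargets", "PerturbationExperiment",
          function(object) metadata(object)$inhibitorTargets)

#' @rdname accessors
#' @export
setMethod("timePoints", "PerturbationExperiment",
          function(object) sort(unique(colData(object)$time)))

#' @rdname accessors
#' @export
setMethod("proteins", "PerturbationExperiment",
          function(object) rownames(object))

#' @rdname accessors
#' @export
setMethod("stimulusIds", "GroundTruth", function(object) object@stimuli)

#' @rdname accessors
#' @export
setMethod("inhibitorIds", "GroundTruth", function(object) object@inhibitors)

#' @rdname accessors
#' @export
setMethod("inhibitorTargets", "GroundTruth",
          function(object) object@inhibitorTargets)

#' @rdname accessors
#' @export
setMethod("timePoints", "GroundTruth", function(object) object@timepoints)

#' @rdname accessors
#' @export
setMethod("proteins", "GroundTruth", function(object) names(object@basal))

#' @rdname accessors
#' @export
setMethod("edges", "SignalingNetwork", function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("edgeCount", "SignalingNetwork",
          function(object) nrow(object@edges))

#' @rdname accessors
#' @export
setMethod("networkNodes", "SignalingNetwork", function(object) {
  data.frame(
    id = c(object@stimulusNodes, object@inhibitedNodes, object@measuredNodes),
    role = rep(c("stimulus", "inhibited_protein", "measured_protein"),
               c(length(object@stimulusNodes), length(object@inhibitedNodes),
                 length(object@measuredNodes))))
})

#' @rdname accessors
#' @export
setMethod("network", "InferredModel", function(object) object@network)

#' @rdname accessors
#' @export
setMethod("booleanTables", "InferredModel", function(object) object@tables)

#' @rdname accessors
#' @export
setMethod("rankedLinks", "InferredModel", function(object) object@rankedLinks)

#' Look up measured intensities
#'
#' `levelAt` returns the intensity of one protein under one condition at
#' one time; `timeCourse` returns the full time course of a condition as a
#' vector named by time point. Both raise a lookup error naming the missing
#' key when the condition or time is absent.
#'
#' @param ds a [PerturbationExperiment-class].
#' @param protein protein id.
#' @param stimuli,inhibitors character vectors of treatment ids (empty for
#'   none).
#' @param time time in minutes.
#' @return `levelAt`: a single intensity; `timeCourse`: a named numeric
#'   vector over all time points.
#' @export
levelAt <- function(ds, protein, stimuli, inhibitors, time) {
  .levelAt(asIndex(ds), protein, conditionKey(stimuli, inhibitors), time)
}

#' @rdname levelAt
#' @export
timeCourse <- function(ds, protein, stimuli, inhibitors) {
  .course(asIndex(ds), protein, conditionKey(stimuli, inhibitors))
}

# Plain-list lookup index over a PerturbationExperiment. The S4 accessors
# are far too slow to sit inside the inference and prediction inner loops,
# so every batch entry point extracts this once and threads it through.
fastIndex <- function(ds) {
  cd <- colData(ds)
  key <- as.character(cd$key)
  time <- as.numeric(cd$time)
  o <- order(key, time)
  idx <- list(x = SummarizedExperiment::assay(ds, "intensity"),
              time = time, byKey = split(o, key[o]),
              tp = sort(unique(time)), prot = rownames(ds),
              stim = stimulusIds(ds), inh = inhibitorIds(ds),
              targets = inhibitorTargets(ds))
  class(idx) <- "perturbIndex"
  idx
}

asIndex <- function(ds) {
  if (inherits(ds, "perturbIndex")) ds else fastIndex(ds)
}

.protRow <- function(idx, protein) {
  i <- match(protein, idx$prot)
  if (is.na(i)) stop("unknown protein '", protein, "'")
  i
}

.levelAt <- function(idx, protein, key, time) {
  j <- idx$byKey[[key]]
  j <- j[idx$time[j] == time]
  if (length(j) != 1L)
    stop("no measurement for condition '", key, "' at t = ", time)
  idx$x[.protRow(idx, protein), j]
}

.course <- function(idx, protein, key) {
  j <- idx$byKey[[key]]            # already ordered by time within key
  if (is.null(j))
    stop("no measurement for condition '", key, "'")
  out <- idx$x[.protRow(idx, protein), j]
  names(out) <- idx$time[j]
  out
}
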