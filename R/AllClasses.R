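#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Measurement-error model for phosphoprotein intensities
#'
#' Luminex-style bead assays carry two error components: an additive
#' technical term with constant standard deviation, and a biological term
#' proportional to the signal (a coefficient of variation). The variance of
#' a measured intensity \eqn{x} is modelled as
#' \deqn{\sigma^2(x) = \mathrm{SD}^2 + (\mathrm{CV}\,x)^2,}
#' the standard additive-plus-proportional form. The defaults (SD = 300
#' intensity units, CV = 8\%) are those of the DREAM4 predictive-signaling
#' assay.
#'
#' @slot technicalSD non-negative numeric; additive technical standard
#'   deviation, in intensity units.
#' @slot biologicalCV numeric in [0, 1); proportional biological coefficient
#'   of variation (dimensionless fraction).
#'
#' @seealso [varianceOf()], [deltaWithVariance()]
#' @export
setClass("ErrorModel",
  representation(technicalSD = "numeric", biologicalCV = "numeric"),
  prototype(technicalSD = 300, biologicalCV = 0.08)
)

setValidity("ErrorModel", function(object) {
  msg <- character(0)
  if (length(object@technicalSD) != 1L || is.na(object@technicalSD) ||
      object@technicalSD < 0)
    msg <- c(msg, "'technicalSD' must be a single non-negative number")
  if (length(object@biologicalCV) != 1L || is.na(object@biologicalCV) ||
      object@biologicalCV < 0 || object@biologicalCV >= 1)
    msg <- c(msg, "'biologicalCV' must be a single number in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn ErrorModel-class Constructor.
#' @param technicalSD additive technical standard deviation (intensity units).
#' @param biologicalCV proportional coefficient of variation (fraction).
#' @return An `ErrorModel` object.
#' @examples
#' em <- ErrorModel()            # DREAM4 defaults: SD = 300, CV = 0.08
#' varianceOf(em, 1000)          # 90000 + 6400
#' @export
ErrorModel <- function(technicalSD = 300, biologicalCV = 0.08) {
  new("ErrorModel", technicalSD = as.numeric(technicalSD),
      biologicalCV = as.numeric(biologicalCV))
}

setMethod("show", "ErrorModel", function(object) {
  cat("ErrorModel: variance(x) = ", object@technicalSD, "^2 + (",
      object@biologicalCV, "*x)^2\n", sep = "")
})

#' Experimental condition (stimulus/inhibitor treatment combination)
#'
#' A treatment condition is the set of applied stimuli (cytokines) together
#' with the set of applied small-molecule inhibitors. The empty set encodes
#' the untreated reference on either axis. Training designs use at most one
#' stimulus and one inhibitor per condition; test (prediction) conditions
#' may combine several of each.
#'
#' @slot stimuli character vector of stimulus ids (possibly empty).
#' @slot inhibitors character vector of inhibitor ids (possibly empty).
#' @export
setClass("Condition",
  representation(stimuli = "character", inhibitors = "character")
)

setValidity("Condition", function(object) {
  msg <- character(0)
  if (anyNA(object@stimuli) || anyNA(object@inhibitors))
    msg <- c(msg, "treatment ids must not be NA")
  if (anyDuplicated(object@stimuli) || anyDuplicated(object@inhibitors))
    msg <- c(msg, "treatment ids must be unique within a condition")
  if (length(msg)) msg else TRUE
})

#' @describeIn Condition-class Constructor; ids are stored sorted so that
#'   conditions compare by content, not by order of entry.
#' @param stimuli,inhibitors character vectors of treatment ids.
#' @return A `Condition` object.
#' @export
Condition <- function(stimuli = character(0), inhibitors = character(0)) {
  new("Condition", stimuli = sort(as.character(stimuli)),
      inhibitors = sort(as.character(inhibitors)))
}

setMethod("show", "Condition", function(object) {
  cat("Condition:", conditionLabel(object), "\n")
})

#' Perturbation dataset as a SummarizedExperiment
#'
#' Container for a stimulus/inhibitor perturbation screen: one assay matrix
#' `intensity` with measured phosphoproteins as rows and one column per
#' (condition, time) sample. `colData` carries the treatment annotation:
#' `stimuli` and `inhibitors` (each a `+`-joined sorted id string, `""` for
#' none), `time` in minutes, and the derived condition `key`. Metadata
#' records the full stimulus/inhibitor panels and the map from each
#' inhibitor to the protein node it targets.
#'
#' Invariants enforced by the validity method: the reference condition
#' (no stimulus, no inhibitor) is present at every time point; every
#' condition present is measured at every time point; all intensities are
#' finite and non-negative; the first time point is 0.
#'
#' @seealso [readMIDAS()], [levelAt()], [timeCourse()]
#' @export
setClass("PerturbationExperiment", contains = "SummarizedExperiment")

setValidity("PerturbationExperiment", function(object) {
  msg <- character(0)
  cd <- colData(object)
  need <- c("stimuli", "inhibitors", "time", "key")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain columns:", paste(need, collapse = ", ")))
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  x <- SummarizedExperiment::assay(object, "intensity")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique protein rownames are required")
  if (any(!is.finite(x)) || any(x < 0))
    msg <- c(msg, "all intensities must be finite and >= 0")
  tp <- sort(unique(cd$time))
  if (length(tp) == 0L || tp[1L] != 0)
    msg <- c(msg, "the first time point must be 0")
  refKey <- conditionKey(character(0), character(0))
  if (!all(tp %in% cd$time[cd$key == refKey]))
    msg <- c(msg, "the reference condition (no stimulus, no inhibitor) must be measured at every time point")
  tab <- table(cd$key, cd$time)
  if (any(tab != 1L))
    msg <- c(msg, "every condition must be measured exactly once at every time point")
  mt <- metadata(object)
  if (!all(c("stimulusIds", "inhibitorIds", "inhibitorTargets") %in% names(mt)))
    msg <- c(msg, "metadata must record stimulusIds, inhibitorIds and inhibitorTargets")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PerturbationExperiment", function(object) {
  cd <- colData(object)
  cat("PerturbationExperiment:", nrow(object), "proteins,",
      length(unique(cd$key)), "conditions,",
      length(unique(cd$time)), "time points\n")
  cat("  proteins:  ", paste(rownames(object), collapse = ", "), "\n")
  cat("  stimuli:   ", paste(stimulusIds(object), collapse = ", "), "\n")
  cat("  inhibitors:", paste(inhibitorIds(object), collapse = ", "), "\n")
  cat("  times (min):", paste(timePoints(object), collapse = ", "), "\n")
})

#' Per-protein Boolean table of stimulus/inhibitor actions
#'
#' For one measured protein, the table holds a cell `[s, v]` for every
#' (stimulus, inhibitor) pair: `s = 1` if the stimulus significantly raises
#' the protein (it is constant down a column, depending on the stimulus
#' only), and `v = 1` if, given an acting stimulus, the inhibitor
#' significantly lowers the level relative to the stimulus-alone course.
#' `s = 0` forces `v = 0` for the whole column. `mediators` records, per
#' stimulus, inhibitors routed to this protein by the network-pruning step
#' (in addition to the table's own `v = 1` cells) so prediction follows the
#' mediated route.
#'
#' @slot protein protein id.
#' @slot s named integer vector (0/1) over stimuli.
#' @slot v integer matrix (0/1), inhibitors x stimuli.
#' @slot mediators named list: stimulus id -> character vector of inhibitor
#'   ids added by pruning.
#' @seealso [buildBooleanTable()], [tableToLinks()]
#' @export
setClass("BooleanTable",
  representation(protein = "character", s = "integer", v = "matrix",
                 mediators = "list")
)

setValidity("BooleanTable", function(object) {
  msg <- character(0)
  s <- object@s; v <- object@v
  if (is.null(names(s)) || is.null(colnames(v)) || is.null(rownames(v)))
    return("s needs stimulus names; v needs inhibitor rownames and stimulus colnames")
  if (!identical(names(s), colnames(v)))
    msg <- c(msg, "columns of v must match names of s")
  if (!all(s %in% c(0L, 1L)) || !all(v %in% c(0L, 1L)))
    msg <- c(msg, "s and v entries must be 0/1")
  bad <- names(s)[s == 0L & colSums(v) > 0L]
  if (length(bad))
    msg <- c(msg, paste0("s = 0 implies v = 0 for the whole column (violated for: ",
                         paste(bad, collapse = ", "), ")"))
  if (!identical(sort(names(object@mediators)), sort(names(s))))
    msg <- c(msg, "mediators must have one entry per stimulus")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BooleanTable", function(object) {
  cat("BooleanTable for protein", object@protein, "\n")
  cells <- matrix(paste(rep(object@s, each = nrow(object@v)), object@v, sep = ","),
                  nrow = nrow(object@v),
                  dimnames = dimnames(object@v))
  print(as.data.frame(cells))
  med <- Filter(length, object@mediators)
  if (length(med))
    cat("pruning mediators:",
        paste(vapply(names(med), function(i)
          paste0(i, "->", paste(med[[i]], collapse = "/")), character(1)),
          collapse = "; "), "\n")
})

#' Cause-effect signaling network
#'
#' Directed graph over three node roles: stimuli (cytokines), inhibited
#' proteins (the targets of the small-molecule inhibitors) and measured
#' phosphoproteins. Every path from a stimulus to a measured protein has
#' length 1 (a direct link) or 2 (mediated by exactly one inhibited
#' protein). A node may be both inhibited and measured.
#'
#' @slot stimulusNodes,inhibitedNodes,measuredNodes character vectors of
#'   node ids per role.
#' @slot edges data.frame with columns `from`, `to`.
#' @seealso [reconstructNetwork()], [writeSIF()]
#' @export
setClass("SignalingNetwork",
  representation(stimulusNodes = "character", inhibitedNodes = "character",
                 measuredNodes = "character", edges = "data.frame")
)

setValidity("SignalingNetwork", function(object) {
  msg <- character(0)
  e <- object@edges
  if (!identical(colnames(e), c("from", "to")))
    return("edges must be a data.frame with columns 'from' and 'to'")
  srcOK <- e$from %in% c(object@stimulusNodes, object@inhibitedNodes)
  if (!all(srcOK))
    msg <- c(msg, "every edge source must be a stimulus or an inhibited protein")
  tgtOK <- e$to %in% c(object@inhibitedNodes, object@measuredNodes)
  if (!all(tgtOK))
    msg <- c(msg, "every edge target must be an inhibited or a measured protein")
  if (any(e$from %in% object@inhibitedNodes &
          !(e$to %in% object@measuredNodes)))
    msg <- c(msg, "edges out of inhibited proteins must end at measured proteins")
  if (anyDuplicated(paste(e$from, e$to)))
    msg <- c(msg, "duplicate edges are not allowed")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SignalingNetwork", function(object) {
  cat("SignalingNetwork:", edgeCount(object), "edges over",
      length(object@stimulusNodes), "stimuli,",
      length(object@inhibitedNodes), "inhibited and",
      length(object@measuredNodes), "measured proteins\n")
  if (nrow(object@edges))
    cat(paste0("  ", object@edges$from, " -> ", object@edges$to, collapse = "\n"), "\n")
})

#' Result of a network reconstruction
#'
#' Bundles everything inference at one significance level k produces: the
#' per-protein Boolean tables (with pruning mediators filled in), the merged
#' and pruned network, the pre-pruning link paths per protein, and the links
#' ranked by the largest k still admitting them.
#'
#' @slot network [SignalingNetwork-class] after pruning.
#' @slot tables named list of [BooleanTable-class], one per protein.
#' @slot paths named list, per protein, of pre-pruning link paths (each a
#'   character vector of 2 or 3 node ids).
#' @slot rankedLinks data.frame with columns `path`, `k_upper` (and
#'   `in_canonical` when an annotation network is supplied), sorted by
#'   `k_upper` decreasing.
#' @slot k the significance multiplier used.
#' @slot errorModel the [ErrorModel-class] used.
#' @export
setClass("InferredModel",
  representation(network = "SignalingNetwork", tables = "list",
                 paths = "list", rankedLinks = "data.frame",
                 k = "numeric", errorModel = "ErrorModel")
)

setMethod("show", "InferredModel", function(object) {
  cat("InferredModel (k = ", object@k, "): ", sep = "")
  show(object@network)
  if (nrow(object@rankedLinks)) {
    cat("Top-ranked links (k_upper):\n")
    top <- utils::head(object@rankedLinks, 5L)
    cat(paste0("  ", top$path, "  ", signif(top$k_upper, 4), collapse = "\n"), "\n")
  }
})

#' Score report for a set of predictions
#'
#' Evaluation of multi-perturbation predictions against measurements under
#' the error model: per-prediction normalized errors (NE), per-protein
#' normalized squared errors (NSE = mean NE^2), resampling-null p-values,
#' the combined Prediction Score and the edge-penalized Overall Score.
#'
#' @slot perPredictionNE data.frame: protein, stimuli, inhibitors, time_min,
#'   predicted, measured, ne.
#' @slot perProteinNSE named numeric.
#' @slot pValues named numeric in (0, 1].
#' @slot predictionScore,overallScore numeric scalars.
#' @slot r cost per network edge used in the Overall Score.
#' @slot edgeCount integer.
#' @slot meanNE,medianNE numeric scalars over all predictions.
#' @slot nullDraws,seed resampling-null configuration.
#' @export
setClass("ScoreReport",
  representation(perPredictionNE = "data.frame", perProteinNSE = "numeric",
                 pValues = "numeric", predictionScore = "numeric",
                 overallScore = "numeric", r = "numeric",
                 edgeCount = "integer", meanNE = "numeric",
                 medianNE = "numeric", nullDraws = "integer",
                 seed = "integer")
)

setMethod("show", "ScoreReport", function(object) {
  cat("ScoreReport over", nrow(object@perPredictionNE), "predictions,",
      length(object@perProteinNSE), "proteins\n")
  cat(sprintf("  mean NE %.3f | median NE %.3f\n", object@meanNE, object@medianNE))
  cat(sprintf("  Prediction Score %.4f | Overall Score %.4f (r = %g, %d edges)\n",
              object@predictionScore, object@overallScore, object@r,
              object@edgeCount))
})

#' Ground truth for synthetic perturbation experiments
#'
#' Encodes an additive-linear generative model: each protein has a basal
#' level; each (stimulus, protein) link raises the protein by a fixed
#' increment at every post-baseline time; increments add across co-applied
#' stimuli; a mediated link is abolished entirely whenever its mediating
#' inhibited node is inhibited in the condition. Measurement noise is
#' Gaussian with variance given by the error model at the clean level.
#'
#' @slot network the true [SignalingNetwork-class].
#' @slot basal named numeric; basal intensity per protein.
#' @slot effects data.frame: stimulus, protein, effect (intensity
#'   increment at t > 0), mediator (inhibited node id or NA for direct).
#' @slot timepoints numeric, minutes, first element 0.
#' @slot errorModel [ErrorModel-class] used for simulated noise.
#' @slot stimuli,inhibitors id panels; `inhibitorTargets` maps inhibitor id
#'   to its inhibited node.
#' @slot seed integer seed the truth was drawn with.
#' @seealso [sampleGroundTruth()], [simulateDataset()]
#' @export
setClass("GroundTruth",
  representation(network = "SignalingNetwork", basal = "numeric",
                 effects = "data.frame", timepoints = "numeric",
                 errorModel = "ErrorModel", stimuli = "character",
                 inhibitors = "character", inhibitorTargets = "character",
                 seed = "integer")
)

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  ef <- object@effects
  need <- c("stimulus", "protein", "effect", "mediator")
  if (!all(need %in% colnames(ef)))
    return(paste("effects needs columns:", paste(need, collapse = ", ")))
  if (nrow(ef) && any(ef$effect <= 0))
    msg <- c(msg, "effects must be positive")
  if (!all(names(object@inhibitorTargets) == object@inhibitors))
    msg <- c(msg, "inhibitorTargets must be named by the inhibitor panel")
  if (object@timepoints[1L] != 0)
    msg <- c(msg, "first time point must be 0")
  if (nrow(ef)) {
    med <- ifelse(is.na(ef$mediator), "", paste0(ef$mediator, "->"))
    hops <- strsplit(paste0(ef$stimulus, "->", med, ef$protein), "->",
                     fixed = TRUE)
    wantEdges <- unique(unlist(lapply(hops, function(h)
      paste(h[-length(h)], h[-1L], sep = "\r"))))
    haveEdges <- paste(object@network@edges$from, object@network@edges$to,
                       sep = "\r")
    if (!setequal(wantEdges, haveEdges))
      msg <- c(msg, "network edges must be exactly those implied by the effects")
  } else if (nrow(object@network@edges)) {
    msg <- c(msg, "network has edges but no effects are defined")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@effects), "links over",
      length(object@stimuli), "stimuli,", length(object@inhibitors),
      "inhibitors,", length(object@basal), "proteins; seed",
      object@seed, "\n")
})
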