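#' Isolate the subnetwork relevant to one prediction
#'
#' For a protein and a combinatorial condition (stimulus set `I`, inhibitor
#' set `J`), keeps only the nodes and edges that route the applied stimuli
#' to the protein: the protein itself, the stimuli in `I` linked to it, and
#' the inhibited nodes targeted by inhibitors in `J` lying on those paths.
#' Inhibitors with no path to the protein are excluded.
#'
#' @param net a [SignalingNetwork-class].
#' @param protein protein id (must be a measured node).
#' @param I character vector of stimulus ids.
#' @param J character vector of inhibitor ids.
#' @param inhibitorTargets named character, inhibitor id -> inhibited node.
#' @return List with `nodes` (character) and `edges` (data.frame).
#' @export
isolateSubnetwork <- function(net, protein, I, J, inhibitorTargets) {
  if (!(protein %in% net@measuredNodes))
    stop("unknown protein '", protein, "'")
  e <- edges(net)
  jNodes <- unname(inhibitorTargets[intersect(J, names(inhibitorTargets))])
  keepE <- e[0, ]
  nodes <- protein
  for (i in intersect(I, net@stimulusNodes)) {
    if (any(e$from == i & e$to == protein)) {
      keepE <- rbind(keepE, data.frame(from = i, to = protein))
      nodes <- c(nodes, i)
    }
    mids <- intersect(e$to[e$from == i], net@inhibitedNodes)
    mids <- mids[vapply(mids, function(q)
      any(e$from == q & e$to == protein), logical(1))]
    mids <- intersect(mids, jNodes)
    for (q in mids) {
      keepE <- rbind(keepE,
                     data.frame(from = c(i, q), to = c(q, protein)))
      nodes <- c(nodes, i, q)
    }
  }
  keepE <- unique(keepE)
  rownames(keepE) <- NULL
  list(nodes = unique(nodes), edges = keepE)
}

#' Active stimuli and their mediating inhibitors for a prediction
#'
#' From the Boolean table of the protein (as updated by reconstruction):
#' the active set `A` contains the applied stimuli with `s = 1`; for each
#' active stimulus, the mediators are the applied inhibitors with
#' `v = 1` for that stimulus (plus any recorded by the pruning step).
#' An active stimulus with no applied mediator keeps its full effect and is
#' read from the stimulus-alone training condition.
#'
#' @param tables named list of [BooleanTable-class] from reconstruction.
#' @param protein protein id.
#' @param I,J character vectors: applied stimuli and inhibitors.
#' @return List with `active` (character vector) and `mediators` (named
#'   list: stimulus -> character vector of mediating inhibitors in `J`,
#'   possibly empty).
#' @export
activeStimuliAndMediators <- function(tables, protein, I, J) {
  tb <- tables[[protein]]
  if (is.null(tb)) stop("no Boolean table for protein '", protein, "'")
  I <- intersect(I, names(tb@s))
  A <- I[tb@s[I] == 1L]
  meds <- lapply(A, function(i) {
    m <- rownames(tb@v)[tb@v[, i] == 1L]
    sort(intersect(union(m, tb@mediators[[i]]), J))
  })
  names(meds) <- A
  list(active = A, mediators = meds)
}

#' Reference level of a protein under an inhibitor combination
#'
#' The baseline from which stimulus effects are added. With inhibitors in
#' `J` linked to the protein, the base reference is the mean over those
#' inhibitors of the no-stimulus/inhibitor-alone level; otherwise it is the
#' untreated level. Additionally, when the reconstructed network says some
#' training stimuli do not affect the protein (`s = 0`), those conditions
#' measure the same underlying baseline, so their levels (under the same
#' inhibitor context) are averaged in — using all conditions the network
#' declares uninformative sharpens the reference estimate.
#'
#' @param ds a [PerturbationExperiment-class].
#' @param tables named list of [BooleanTable-class] from reconstruction.
#' @param protein protein id.
#' @param J character vector of applied inhibitor ids.
#' @param time time in minutes.
#' @return A single intensity.
#' @export
referenceLevel <- function(ds, tables, protein, J, time) {
  idx <- asIndex(ds)
  tb <- tables[[protein]]
  if (is.null(tb)) stop("no Boolean table for protein '", protein, "'")
  linked <- linkedInhibitors(tb, J)
  if (length(linked))
    mean(vapply(linked, function(j)
      inhibitedReference(idx, tb, protein, j, time), numeric(1)))
  else
    plainReference(idx, tb, protein, time)
}

# inhibitors in J linked to the protein (mediating some stimulus, by the
# table's v cells or the pruning record)
linkedInhibitors <- function(tb, J) {
  lnk <- rownames(tb@v)[rowSums(tb@v) > 0L]
  lnk <- union(lnk, unlist(tb@mediators, use.names = FALSE))
  sort(intersect(J, lnk))
}

# mean of the untreated level and the non-affecting stimulus-alone levels
plainReference <- function(idx, tb, protein, time) {
  vals <- .levelAt(idx, protein, "|", time)
  for (i in names(tb@s)[tb@s == 0L])
    vals <- c(vals, .levelAt(idx, protein, paste0(i, "|"), time))
  mean(vals)
}

# same, within the context of one applied inhibitor
inhibitedReference <- function(idx, tb, protein, j, time) {
  vals <- .levelAt(idx, protein, paste0("|", j), time)
  for (i in names(tb@s)[tb@s == 0L])
    vals <- c(vals, .levelAt(idx, protein, paste0(i, "|", j), time))
  mean(vals)
}

#' Predict a protein level under a combinatorial condition
#'
#' Linear superposition of single-perturbation training data routed
#' through the reconstructed network. With active stimuli `A` and, for
#' each `i` in `A`, the applied mediating inhibitors `M_i`:
#' \deqn{\hat X(t|I,J) = R(t|J) + \sum_{i \in A} \overline{\big[X(t|i,m) -
#'   R(t|m)\big]}_{m \in M_i},}
#' where the overline averages over `M_i` (a stimulus whose path is not
#' blocked by any applied inhibitor contributes its stimulus-alone
#' increment), and `R` are reference levels from [referenceLevel()]. When
#' no stimulus is active the prediction is the reference itself. At
#' t = 0 no stimulus has acted yet, so the prediction equals the
#' reference. Negative values are clamped to 0.
#'
#' For the classic two-stimulus case sharing one mediating inhibitor
#' (both paths through the same inhibited node, that inhibitor applied),
#' the formula reduces to
#' `X(t|i1,j) + X(t|i2,j) - X(t|0,j)`: the inhibitor's effect enters the
#' sum twice, so the inhibitor-alone level is subtracted once.
#'
#' @param ds a [PerturbationExperiment-class] of training data.
#' @param fit an [InferredModel-class] from [reconstructNetwork()].
#' @param protein protein id.
#' @param stimuli,inhibitors the combinatorial condition (character
#'   vectors of ids).
#' @param time time in minutes.
#' @return List: `protein`, `stimuli`, `inhibitors`, `time_min`,
#'   `predicted`, `reference_used`, `active_stimuli`, `mediators`.
#' @examples
#' truth <- sampleGroundTruth(seed = 11)
#' ds <- simulateDataset(truth, noise = FALSE)
#' fit <- reconstructNetwork(ds, ErrorModel(), k = 2.5)
#' predictCondition(ds, fit, proteins(ds)[1],
#'                  stimuli = stimulusIds(ds)[1:2],
#'                  inhibitors = inhibitorIds(ds)[1], time = 30)$predicted
#' @export
predictCondition <- function(ds, fit, protein, stimuli = character(0),
                             inhibitors = character(0), time) {
  idx <- asIndex(ds)
  tables <- booleanTables(fit)
  I <- sort(unique(as.character(stimuli)))
  J <- sort(unique(as.character(inhibitors)))
  am <- activeStimuliAndMediators(tables, protein, I, J)
  R <- referenceLevel(idx, tables, protein, J, time)
  pred <- R
  active <- if (time > 0) am$active else character(0)
  for (i in active) {
    ms <- am$mediators[[i]]
    contrib <- if (length(ms)) {
      mean(vapply(ms, function(m)
        .levelAt(idx, protein, paste0(i, "|", m), time) -
          inhibitedReference(idx, tables[[protein]], protein, m, time),
        numeric(1)))
    } else {
      .levelAt(idx, protein, paste0(i, "|"), time) -
        plainReference(idx, tables[[protein]], protein, time)
    }
    pred <- pred + contrib
  }
  list(protein = protein, stimuli = I, inhibitors = J, time_min = time,
       predicted = max(pred, 0), reference_used = R,
       active_stimuli = am$active, mediators = am$mediators)
}

#' Predict a batch of combinatorial conditions
#'
#' Applies [predictCondition()] to each row of a task table, preserving
#' row order. Errors are aggregated with the offending task index.
#'
#' @param ds a [PerturbationExperiment-class] of training data.
#' @param fit an [InferredModel-class].
#' @param tasks data.frame with columns `protein`, `stimuli`, `inhibitors`
#'   (`+`-joined id strings, `""` for none) and `time_min`.
#' @return data.frame with one row per task: `protein`, `stimuli`,
#'   `inhibitors`, `time_min`, `predicted`, `reference_used`,
#'   `active_stimuli`, `mediators`.
#' @seealso [writePredictions()]
#' @export
predictBatch <- function(ds, fit, tasks) {
  need <- c("protein", "stimuli", "inhibitors", "time_min")
  if (!all(need %in% colnames(tasks)))
    stop("tasks needs columns: ", paste(need, collapse = ", "))
  idx <- asIndex(ds)
  rows <- vector("list", nrow(tasks))
  errs <- character(0)
  for (r in seq_len(nrow(tasks))) {
    rec <- tryCatch(
      predictCondition(idx, fit, tasks$protein[r],
                       splitIds(tasks$stimuli[r]),
                       splitIds(tasks$inhibitors[r]),
                       tasks$time_min[r]),
      error = function(e) e)
    if (inherits(rec, "error")) {
      errs <- c(errs, paste0("task ", r, ": ", conditionMessage(rec)))
      next
    }
    rows[[r]] <- data.frame(
      protein = rec$protein,
      stimuli = joinIds(rec$stimuli),
      inhibitors = joinIds(rec$inhibitors),
      time_min = rec$time_min,
      predicted = rec$predicted,
      reference_used = rec$reference_used,
      active_stimuli = joinIds(rec$active_stimuli),
      mediators = paste(vapply(names(rec$mediators), function(i)
        paste0(i, ":", paste(rec$mediators[[i]], collapse = "/")),
        character(1)), collapse = ";"))
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein = character(0), stimuli = character(0),
                      inhibitors = character(0), time_min = numeric(0),
                      predicted = numeric(0), reference_used = numeric(0),
                      active_stimuli = character(0), mediators = character(0))
  rownames(out) <- NULL
  out
}

#' Write predictions as CSV
#'
#' Deterministic row order: protein, then condition key, then time.
#'
#' @param records output of [predictBatch()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePredictions <- function(records, path) {
  o <- order(records$protein, records$stimuli, records$inhibitors,
             records$time_min)
  out <- records[o, c("protein", "stimuli", "inhibitors", "time_min",
                      "predicted")]
  names(out)[names(out) == "predicted"] <- "predicted_value"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
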