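#' Draw a random ground-truth signaling network
#'
#' Samples an additive-linear ground truth emulating the DREAM4 predictive
#' signaling design: a panel of stimuli, a panel of inhibitors (each
#' naming its inhibited target node), and a panel of measured proteins.
#' Each (stimulus, protein) pair independently receives no link (with
#' probability `1 - pDirect - pMediated`), a direct link, or a mediated
#' link through a uniformly chosen inhibited node. Effect sizes are drawn
#' uniformly in `[1, 1.3] * effectScale * technicalSD`, so `effectScale`
#' is a lower bound on the effect in technical-SD units. Basal levels are
#' drawn uniformly in [500, 1500] intensity units.
#'
#' @param nStimuli,nInhibitors,nProteins panel sizes (defaults 4, 4, 7,
#'   the DREAM4 design).
#' @param pDirect,pMediated per-pair link probabilities; their sum must
#'   not exceed 1.
#' @param effectScale effect size as a multiple of the technical SD
#'   (default 10).
#' @param timepoints measurement times in minutes, first element 0
#'   (default `c(0, 30, 180)`).
#' @param errorModel the [ErrorModel-class] simulated noise will follow.
#' @param seed integer seed; the same seed reproduces the same truth.
#' @return A [GroundTruth-class].
#' @examples
#' truth <- sampleGroundTruth(seed = 1)
#' truth
#' @export
sampleGroundTruth <- function(nStimuli = 4, nInhibitors = 4, nProteins = 7,
                              pDirect = 0.15, pMediated = 0.15,
                              effectScale = 10,
                              timepoints = c(0, 30, 180),
                              errorModel = ErrorModel(), seed = 1L) {
  stopifnot(pDirect >= 0, pMediated >= 0, effectScale > 0)
  if (pDirect + pMediated > 1)
    stop("pDirect + pMediated must not exceed 1")
  stimuli <- paste0("S", seq_len(nStimuli))
  targets <- paste0("K", seq_len(nInhibitors))
  inhibitors <- paste0(targets, "i")
  names(targets) <- inhibitors
  prots <- paste0("P", seq_len(nProteins))
  withSeed(seed, {
    basal <- stats::setNames(stats::runif(nProteins, 500, 1500), prots)
    rows <- list()
    for (i in stimuli) for (p in prots) {
      u <- stats::runif(1)
      if (u >= pDirect + pMediated) next
      med <- if (u < pDirect) NA_character_ else sample(targets, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        stimulus = i, protein = p,
        effect = stats::runif(1, 1, 1.3) * effectScale *
          errorModel@technicalSD,
        mediator = med)
    }
    effects <- if (length(rows)) do.call(rbind, rows)
    else data.frame(stimulus = character(0), protein = character(0),
                    effect = numeric(0), mediator = character(0))
    rownames(effects) <- NULL
    net <- truthNetwork(effects, stimuli, targets, prots)
    new("GroundTruth", network = net, basal = basal, effects = effects,
        timepoints = as.numeric(timepoints), errorModel = errorModel,
        stimuli = stimuli, inhibitors = inhibitors,
        inhibitorTargets = targets, seed = as.integer(seed))
  })
}

truthNetwork <- function(effects, stimuli, targets, prots) {
  paths <- lapply(seq_len(nrow(effects)), function(r) {
    if (is.na(effects$mediator[r]))
      c(effects$stimulus[r], effects$protein[r])
    else c(effects$stimulus[r], effects$mediator[r], effects$protein[r])
  })
  medN <- unique(effects$mediator[!is.na(effects$mediator)])
  new("SignalingNetwork",
      stimulusNodes = sort(unique(effects$stimulus)),
      inhibitedNodes = sort(medN),
      measuredNodes = sort(prots),
      edges = uniqueEdges(paths))
}

#' Paths of a ground truth, as strings
#'
#' One `"S->P"` or `"S->K->P"` string per true link, matching the path
#' strings of [rankedLinks()] and `InferredModel@paths`.
#'
#' @param truth a [GroundTruth-class].
#' @return Character vector of path strings.
#' @export
groundTruthPaths <- function(truth) {
  ef <- if (is(truth, "GroundTruth")) truth@effects else truth
  if (!nrow(ef)) return(character(0))
  med <- ifelse(is.na(ef$mediator), "", paste0(ef$mediator, "->"))
  paste0(ef$stimulus, "->", med, ef$protein)
}

# Clean (noise-free) level of one protein under one condition at one time.
cleanLevel <- function(truth, protein, stimuli, inhibitors, time) {
  x <- truth@basal[[protein]]
  if (time == 0) return(x)
  blocked <- unname(truth@inhibitorTargets[intersect(
    inhibitors, names(truth@inhibitorTargets))])
  ef <- truth@effects
  sel <- ef$protein == protein & ef$stimulus %in% stimuli &
    !(ef$mediator %in% blocked & !is.na(ef$mediator))
  x + sum(ef$effect[sel])
}

#' Simulate a single-perturbation training dataset
#'
#' Generates the full single-perturbation design from a ground truth: the
#' reference condition, every stimulus alone, every inhibitor alone, and
#' every stimulus x inhibitor pair (for the default 4 x 4 panels: 25
#' conditions), each measured at every time point. Clean levels follow the
#' additive model (basal at t = 0; basal plus the unblocked stimulus
#' effects at t > 0). With `noise = TRUE`, independent Gaussian noise with
#' variance given by the truth's error model at the clean level is added
#' and values are clamped at 0.
#'
#' @param truth a [GroundTruth-class].
#' @param noise logical; add measurement noise (default TRUE).
#' @param seed integer seed for the noise draws; defaults to a child of
#'   the truth's seed, so the same truth yields the same dataset.
#' @return A [PerturbationExperiment-class].
#' @examples
#' ds <- simulateDataset(sampleGroundTruth(seed = 1), noise = FALSE)
#' ds
#' @export
simulateDataset <- function(truth, noise = TRUE,
                            seed = childSeed(truth@seed, 1L)) {
  conds <- trainingConditions(truth)
  simulateConditions(truth, conds, noise = noise, seed = seed)
}

trainingConditions <- function(truth) {
  conds <- list(list(s = character(0), j = character(0)))
  for (i in truth@stimuli)
    conds[[length(conds) + 1L]] <- list(s = i, j = character(0))
  for (j in truth@inhibitors)
    conds[[length(conds) + 1L]] <- list(s = character(0), j = j)
  for (i in truth@stimuli) for (j in truth@inhibitors)
    conds[[length(conds) + 1L]] <- list(s = i, j = j)
  conds
}

simulateConditions <- function(truth, conds, noise, seed) {
  prots <- proteins(truth)
  tp <- truth@timepoints
  n <- length(conds) * length(tp)
  stimuli <- character(n); inhibitors <- character(n); time <- numeric(n)
  x <- matrix(0, nrow = length(prots), ncol = n,
              dimnames = list(prots, NULL))
  col <- 0L
  for (cnd in conds) for (t in tp) {
    col <- col + 1L
    stimuli[col] <- joinIds(cnd$s)
    inhibitors[col] <- joinIds(cnd$j)
    time[col] <- t
    x[, col] <- vapply(prots, function(p)
      cleanLevel(truth, p, cnd$s, cnd$j, t), numeric(1))
  }
  if (noise) {
    x <- withSeed(seed, {
      noisy <- x + stats::rnorm(length(x),
                                sd = sqrt(varianceOf(truth@errorModel, x)))
      matrix(pmax(noisy, 0), nrow = nrow(x), dimnames = dimnames(x))
    })
  }
  PerturbationExperiment(x, stimuli = stimuli, inhibitors = inhibitors,
                         time = time, stimulusIds = truth@stimuli,
                         inhibitorIds = truth@inhibitors,
                         inhibitorTargets = truth@inhibitorTargets)
}

#' Default combinatorial test design
#'
#' Twenty pairwise test conditions in the DREAM4 layout: five stimulus
#' sets (each single stimulus plus the pair of the last two) crossed with
#' four inhibitor pairs (the last two inhibitors crossed with the first
#' two), at every post-baseline time point of the truth. With fewer than
#' two stimuli or inhibitors the crossings degenerate gracefully to the
#' available sets.
#'
#' @param truth a [GroundTruth-class].
#' @return data.frame of tasks with columns `protein`, `stimuli`,
#'   `inhibitors`, `time_min` (one row per protein, condition and t > 0).
#' @export
defaultTestTasks <- function(truth) {
  ns <- length(truth@stimuli); ni <- length(truth@inhibitors)
  stimSets <- as.list(truth@stimuli)
  if (ns >= 2L)
    stimSets <- c(stimSets, list(truth@stimuli[c(ns - 1L, ns)]))
  inhSets <- if (ni >= 4L) {
    out <- list()
    for (a in truth@inhibitors[3:4]) for (b in truth@inhibitors[1:2])
      out[[length(out) + 1L]] <- c(b, a)
    out
  } else if (ni >= 2L) {
    utils::combn(truth@inhibitors, 2L, simplify = FALSE)
  } else if (ni == 1L) list(truth@inhibitors) else list(character(0))
  tp <- truth@timepoints[truth@timepoints > 0]
  rows <- list()
  for (p in proteins(truth)) for (s in stimSets) for (j in inhSets)
    for (t in tp)
      rows[[length(rows) + 1L]] <- data.frame(
        protein = p, stimuli = joinIds(s), inhibitors = joinIds(j),
        time_min = t)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clean or noisy truth values for combinatorial test conditions
#'
#' Evaluates the additive model at multi-stimulus/multi-inhibitor
#' conditions: basal plus the sum of effects of the applied stimuli whose
#' mediating node is not inhibited in the condition. With `noise = TRUE`,
#' measurement noise is added as in [simulateDataset()] (this is how the
#' "measured" test values for scoring are produced).
#'
#' @param truth a [GroundTruth-class].
#' @param tasks data.frame with columns `protein`, `stimuli`,
#'   `inhibitors`, `time_min` (e.g. from [defaultTestTasks()]).
#' @param noise logical; add measurement noise (default FALSE: clean
#'   ground truth).
#' @param seed integer seed for the noise draws.
#' @return The `tasks` data.frame with a `measured` column appended.
#' @export
simulateTestTruth <- function(truth, tasks, noise = FALSE,
                              seed = childSeed(truth@seed, 2L)) {
  known <- c(truth@stimuli, truth@inhibitors)
  vals <- vapply(seq_len(nrow(tasks)), function(r) {
    s <- splitIds(tasks$stimuli[r]); j <- splitIds(tasks$inhibitors[r])
    if (!all(c(s, j) %in% known))
      stop("unknown treatment id in task ", r, ": ",
           paste(setdiff(c(s, j), known), collapse = ", "))
    if (!(tasks$protein[r] %in% proteins(truth)))
      stop("unknown protein in task ", r, ": ", tasks$protein[r])
    cleanLevel(truth, tasks$protein[r], s, j, tasks$time_min[r])
  }, numeric(1))
  if (noise)
    vals <- withSeed(seed, pmax(vals + stats::rnorm(
      length(vals), sd = sqrt(varianceOf(truth@errorModel, vals))), 0))
  out <- tasks
  out$measured <- vals
  out
}

#' Write a named fixture scenario to disk
#'
#' Generates and writes a complete, reproducible test scenario: the MIDAS
#' training file (`training.csv`), the combinatorial test-condition list
#' (`test_conditions.csv`), the ground-truth network (`truth_network.sif`)
#' and the clean test-truth values (`test_truth.csv`). Profiles:
#' \describe{
#'   \item{`dream4-like`}{4 stimuli / 4 inhibitors / 7 proteins, noisy
#'     training data, effects at 10 technical SDs.}
#'   \item{`tiny`}{2 stimuli / 1 inhibitor / 2 proteins, noisy.}
#'   \item{`no-signal`}{4 / 4 / 7 with no links and no noise: a flat
#'     dataset from which any positive k yields an empty network.}
#' }
#'
#' @param profile one of `"dream4-like"`, `"tiny"`, `"no-signal"`.
#' @param seed integer seed; same seed, byte-identical files.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
makeFixture <- function(profile = c("dream4-like", "tiny", "no-signal"),
                        seed = 1L, dir = ".") {
  profile <- match.arg(profile)
  truth <- switch(profile,
    "dream4-like" = sampleGroundTruth(seed = seed),
    "tiny" = sampleGroundTruth(2, 1, 2, pDirect = 0.4, pMediated = 0.3,
                               seed = seed),
    "no-signal" = sampleGroundTruth(pDirect = 0, pMediated = 0,
                                    seed = seed))
  noise <- profile != "no-signal"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulateDataset(truth, noise = noise)
  tasks <- defaultTestTasks(truth)
  paths <- c(
    training = file.path(dir, "training.csv"),
    test_conditions = file.path(dir, "test_conditions.csv"),
    truth_network = file.path(dir, "truth_network.sif"),
    test_truth = file.path(dir, "test_truth.csv"))
  writeMIDAS(ds, paths[["training"]])
  conds <- unique(tasks[, c("stimuli", "inhibitors")])
  utils::write.csv(conds, paths[["test_conditions"]], row.names = FALSE,
                   quote = FALSE)
  writeSIF(truth@network, paths[["truth_network"]])
  utils::write.csv(simulateTestTruth(truth, tasks),
                   paths[["test_truth"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
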