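# Fixture builders shared across the test files. All data are generated in
# code; nothing is read from disk except files the tests themselves write.

# Dataset from explicit time courses. `courses` is a named list keyed by
# condition key "stimuli|inhibitors" ("" for none, ids "+"-joined); each
# element is a numeric matrix proteins x timepoints (or a numeric vector
# for a single protein, named "P").
courseDataset <- function(courses, timepoints = c(0, 30, 180),
                          proteins = NULL, ...) {
  mats <- lapply(courses, function(x) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                     dimnames = list("P", NULL))
    if (!is.null(proteins) && nrow(x) == length(proteins))
      rownames(x) <- proteins
    x
  })
  if (is.null(proteins)) proteins <- rownames(mats[[1]])
  nT <- length(timepoints)
  stim <- character(0); inh <- character(0); time <- numeric(0)
  cols <- NULL
  for (key in names(mats)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    s <- if (length(parts) >= 1) parts[1] else ""
    j <- if (length(parts) >= 2) parts[2] else ""
    stim <- c(stim, rep(s, nT)); inh <- c(inh, rep(j, nT))
    time <- c(time, timepoints)
    cols <- cbind(cols, mats[[key]][proteins, , drop = FALSE])
  }
  PerturbationExperiment(cols, stimuli = stim, inhibitors = inh,
                         time = time, ...)
}

# Boolean table built directly (bypassing inference) for unit tests of the
# network rules and the prediction formula.
manualTable <- function(protein, stimuli, inhibitors, sOn = character(0),
                        vOn = list()) {
  s <- stats::setNames(as.integer(stimuli %in% sOn), stimuli)
  v <- matrix(0L, length(inhibitors), length(stimuli),
              dimnames = list(inhibitors, stimuli))
  for (i in names(vOn)) v[vOn[[i]], i] <- 1L
  meds <- stats::setNames(rep(list(character(0)), length(stimuli)), stimuli)
  new("BooleanTable", protein = protein, s = s, v = v, mediators = meds)
}

# Ground truth with the classic AKT-prediction topology: two growth-factor
# stimuli converge on AKT through one inhibited kinase (PI3K), one of them
# also drives a second measured kinase (MEK12) directly, and that kinase
# mediates a link to a downstream protein (ERK12). The second inhibitor
# (MEKi) therefore has no path to AKT.
aktTruth <- function(seed = 1L, effectScale = 10) {
  em <- ErrorModel()
  eff <- effectScale * em@technicalSD
  effects <- data.frame(
    stimulus = c("TGFa", "IGF1", "TGFa", "TGFa"),
    protein = c("AKT", "AKT", "MEK12", "ERK12"),
    effect = eff * c(1, 1.1, 1.2, 1.05),
    mediator = c("PI3K", "PI3K", NA, "MEK12"))
  targets <- c(MEKi = "MEK12", PI3Ki = "PI3K")
  paths <- list(c("TGFa", "PI3K", "AKT"), c("IGF1", "PI3K", "AKT"),
                c("TGFa", "MEK12"), c("TGFa", "MEK12", "ERK12"))
  edges <- unique(do.call(rbind, lapply(paths, function(p)
    data.frame(from = p[-length(p)], to = p[-1]))))
  rownames(edges) <- NULL
  net <- new("SignalingNetwork",
             stimulusNodes = c("IGF1", "TGFa"),
             inhibitedNodes = c("MEK12", "PI3K"),
             measuredNodes = c("AKT", "ERK12", "MEK12"),
             edges = edges)
  new("GroundTruth", network = net,
      basal = c(AKT = 700, ERK12 = 900, MEK12 = 1100),
      effects = effects, timepoints = c(0, 30, 180),
      errorModel = em, stimuli = c("IGF1", "TGFa"),
      inhibitors = c("MEKi", "PI3Ki"), inhibitorTargets = targets,
      seed = as.integer(seed))
}

# Flat ground truth (no links) with a controlled basal level, for
# noise-calibration checks.
flatTruth <- function(basal = 1250, nProteins = 7, seed = 1L) {
  tr <- sampleGroundTruth(pDirect = 0, pMediated = 0,
                          nProteins = nProteins, seed = seed)
  tr@basal[] <- basal
  tr
}

# Pre-pruning significance claims of a fit, as strings; the "link set" in
# the sense of the Boolean tables (one claim per s = 1 stimulus and one
# per v = 1 cell).
tableClaims <- function(tables) {
  out <- character(0)
  for (tb in tables) {
    sOn <- names(tb@s)[tb@s == 1L]
    if (length(sOn)) out <- c(out, paste0(tb@protein, ":", sOn))
    idx <- which(tb@v == 1L, arr.ind = TRUE)
    if (nrow(idx))
      out <- c(out, paste0(tb@protein, ":", colnames(tb@v)[idx[, 2]],
                           ":", rownames(tb@v)[idx[, 1]]))
  }
  sort(out)
}

# All inferred pre-pruning paths of a fit, as "A->B(->C)" strings.
fitPaths <- function(fit) {
  sort(unlist(lapply(fit@paths, function(ps)
    vapply(ps, paste, character(1), collapse = "->")), use.names = FALSE))
}
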