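#' Translate a Boolean table into link paths
#'
#' Applies the table-to-subnetwork rules for one protein, per stimulus
#' column: an all-`[0,0]` column yields nothing; a column of all `[1,0]`
#' cells yields a direct link stimulus -> protein; each `[1,1]` cell yields
#' a mediated link stimulus -> inhibited protein -> protein (the middle
#' node is the inhibitor's target). A column containing any `[1,1]` cell
#' yields no direct link.
#'
#' @param table a [BooleanTable-class].
#' @param inhibitorTargets named character mapping inhibitor ids to
#'   inhibited-protein node ids.
#' @return List of paths, each a character vector of node ids (length 2
#'   for direct, 3 for mediated links).
#' @seealso [mergeAndPrune()], [reconstructNetwork()]
#' @export
tableToLinks <- function(table, inhibitorTargets) {
  paths <- list()
  for (i in names(table@s)) {
    if (table@s[[i]] == 0L) next
    js <- rownames(table@v)[table@v[, i] == 1L]
    if (length(js)) {
      for (j in js)
        paths[[length(paths) + 1L]] <-
          c(i, unname(inhibitorTargets[[j]]), table@protein)
    } else {
      paths[[length(paths) + 1L]] <- c(i, table@protein)
    }
  }
  paths
}

#' Merge per-protein subnetworks and prune redundant direct links
#'
#' Takes the union of all proteins' link paths into one directed graph
#' (shared intermediate nodes merged). Then, on the merged graph, whenever
#' a stimulus and a measured protein are connected both by a direct edge
#' and by a two-step path through an inhibited node, the direct edge is
#' pruned: the mediated route carries the prediction. The pruned pair's
#' mediating inhibitors are recorded in that protein's table
#' (`mediators` slot) so prediction routes through them.
#'
#' @param pathsList named list (per protein) of path lists from
#'   [tableToLinks()].
#' @param tables named list of [BooleanTable-class], one per protein.
#' @param inhibitorTargets named character, inhibitor id -> inhibited node.
#' @return List with `network` (a [SignalingNetwork-class]) and `tables`
#'   (the input tables with pruning mediators filled in).
#' @export
mergeAndPrune <- function(pathsList, tables, inhibitorTargets) {
  allPaths <- unlist(pathsList, recursive = FALSE, use.names = FALSE)
  edg <- uniqueEdges(allPaths)
  stimN <- unique(unlist(lapply(allPaths, `[`, 1L)))
  medN <- unique(unlist(lapply(allPaths[lengths(allPaths) == 3L], `[`, 2L)))
  measN <- names(tables)
  inhOf <- split(names(inhibitorTargets), inhibitorTargets)

  # prune direct edges shadowed by a 2-step path through an inhibited node
  if (nrow(edg)) {
    drop <- logical(nrow(edg))
    for (r in seq_len(nrow(edg))) {
      i <- edg$from[r]; p <- edg$to[r]
      if (!(i %in% stimN) || !(p %in% measN)) next
      mids <- intersect(edg$to[edg$from == i], medN)
      mids <- mids[vapply(mids, function(q)
        any(edg$from == q & edg$to == p), logical(1))]
      mids <- setdiff(mids, p)
      if (!length(mids)) next
      drop[r] <- TRUE
      meds <- sort(unique(unlist(inhOf[mids])))
      tb <- tables[[p]]
      tb@mediators[[i]] <- sort(unique(c(tb@mediators[[i]], meds)))
      tables[[p]] <- tb
    }
    edg <- edg[!drop, , drop = FALSE]
    rownames(edg) <- NULL
  }

  net <- new("SignalingNetwork",
             stimulusNodes = sort(stimN %||% character(0)),
             inhibitedNodes = sort(medN %||% character(0)),
             measuredNodes = sort(measN),
             edges = edg)
  list(network = net, tables = tables)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

uniqueEdges <- function(paths) {
  if (!length(paths))
    return(data.frame(from = character(0), to = character(0)))
  e <- do.call(rbind, lapply(paths, function(p)
    cbind(p[-length(p)], p[-1L])))
  e <- unique(data.frame(from = e[, 1L], to = e[, 2L]))
  rownames(e) <- NULL
  e
}

#' Rank links by the largest k still admitting them
#'
#' Each retained link is scored by its upper-limit significance
#' multiplier: a direct link stimulus -> protein by the stimulus
#' k-threshold; a mediated link stimulus -> inhibited node -> protein by
#' the minimum of the stimulus threshold and the mediating inhibitor's
#' threshold (the link survives only while both actions do). Links are
#' sorted by `k_upper` decreasing, ties broken lexicographically by path.
#'
#' @param ds a [PerturbationExperiment-class].
#' @param model an [ErrorModel-class].
#' @param pathsList named list (per protein) of link paths to rank (as
#'   retained after pruning).
#' @param canonical optional [SignalingNetwork-class] or data.frame of
#'   edges used only to annotate each link as inside/outside a literature
#'   network; it never changes the link set.
#' @return data.frame with columns `path`, `k_upper` (and `in_canonical`).
#' @export
rankLinks <- function(ds, model, pathsList, canonical = NULL) {
  idx <- asIndex(ds)
  targets <- idx$targets
  rows <- list()
  for (p in names(pathsList)) {
    for (path in pathsList[[p]]) {
      i <- path[1L]
      kU <- stimulusKThreshold(idx, model, p, i)
      if (length(path) == 3L) {
        js <- names(targets)[targets == path[2L]]
        kJ <- max(vapply(js, function(j)
          inhibitorKThreshold(idx, model, p, i, j), numeric(1)))
        kU <- min(kU, kJ)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(path = pathString(path), k_upper = kU)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(path = character(0), k_upper = numeric(0))
  out <- out[order(-out$k_upper, out$path), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(canonical)) {
    ce <- if (is(canonical, "SignalingNetwork")) edges(canonical) else canonical
    canPaths <- canonicalPathStrings(ce)
    out$in_canonical <- out$path %in% canPaths
  }
  out
}

canonicalPathStrings <- function(ce) {
  direct <- paste0(ce$from, "->", ce$to)
  med <- character(0)
  for (r in seq_len(nrow(ce))) {
    q <- ce$to[r]
    nxt <- ce$to[ce$from == q]
    if (length(nxt))
      med <- c(med, paste0(ce$from[r], "->", q, "->", nxt))
  }
  c(direct, med)
}

#' Reconstruct the signaling network at significance level k
#'
#' The full inference pipeline: build one Boolean table per protein at the
#' given `k`, translate every table into link paths, merge the subnetworks,
#' prune redundant direct links, and rank the retained links by their
#' upper-limit k.
#'
#' @inheritParams rankLinks
#' @param k positive significance multiplier (default 2.5, the value that
#'   balances true against false links on DREAM4-style data).
#' @return An [InferredModel-class].
#' @examples
#' truth <- sampleGroundTruth(seed = 7)
#' ds <- simulateDataset(truth, noise = FALSE)
#' fit <- reconstructNetwork(ds, ErrorModel(), k = 2.5)
#' network(fit)
#' @export
reconstructNetwork <- function(ds, model, k = 2.5, canonical = NULL) {
  stopifnot(length(k) == 1L, k > 0)
  idx <- asIndex(ds)
  targets <- idx$targets
  tables <- lapply(idx$prot, function(p)
    buildBooleanTable(idx, model, p, k))
  names(tables) <- idx$prot
  pathsList <- lapply(tables, tableToLinks, inhibitorTargets = targets)
  merged <- mergeAndPrune(pathsList, tables, targets)
  kept <- retainedPaths(pathsList, merged$network)
  links <- rankLinks(idx, model, kept, canonical = canonical)
  new("InferredModel", network = merged$network, tables = merged$tables,
      paths = pathsList, rankedLinks = links, k = k, errorModel = model)
}

# paths still represented in the pruned network (mediated paths always
# survive; direct paths survive iff their edge was not pruned)
retainedPaths <- function(pathsList, net) {
  e <- edges(net)
  lapply(pathsList, function(paths)
    Filter(function(p) length(p) == 3L ||
             any(e$from == p[1L] & e$to == p[2L]), paths))
}

#' Read and write SIF network files
#'
#' The simple interaction format: one line per edge,
#' `source<TAB>1<TAB>target`. The relation column is always `1`
#' (activating cause-effect link).
#'
#' @param net a [SignalingNetwork-class].
#' @param path file path.
#' @return `writeSIF`: invisibly, `path`; `readSIF`: a data.frame with
#'   columns `from`, `to`.
#' @export
writeSIF <- function(net, path) {
  e <- edges(net)
  lines <- if (nrow(e)) paste(e$from, "1", e$to, sep = "\t") else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSIF
#' @export
readSIF <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(data.frame(from = character(0), to = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(from = vapply(parts, `[`, character(1), 1L),
             to = vapply(parts, `[`, character(1), 3L))
}
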