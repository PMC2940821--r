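# Canonical condition keys: treatments sorted, "+"-joined, "" for none,
# stimulus part and inhibitor part separated by "|".

joinIds <- function(ids) paste(sort(unique(as.character(ids))), collapse = "+")

splitIds <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, "+", fixed = TRUE)[[1L]]
}

conditionKey <- function(stimuli, inhibitors) {
  paste(joinIds(stimuli), joinIds(inhibitors), sep = "|")
}

conditionLabel <- function(cond) {
  s <- joinIds(cond@stimuli); i <- joinIds(cond@inhibitors)
  paste0("[", if (nzchar(s)) s else "none", " / ",
         if (nzchar(i)) i else "none", "]")
}

pathString <- function(path) paste(path, collapse = "->")

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a base seed (kept within 32-bit range).
childSeed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2147483587L
}
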