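# Internal helpers: localized RNG and label utilities.

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards, so every randomized operation is a pure
# function of its seed argument.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic stream of sub-seeds (kept below 2^31).
.deriveSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Relabel a partition so clusters are numbered by first appearance;
# makes partitions from different seeds directly comparable.
.canonicalLabels <- function(labels) {
  first <- unique(labels)
  out <- match(labels, first)
  names(out) <- names(labels)
  as.integer(out)
}

.assertScores <- function(x) {
  if (!is(x, "OrdinalScoreMatrix"))
    stop("expected an OrdinalScoreMatrix")
  validObject(x)
  invisible(x)
}
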