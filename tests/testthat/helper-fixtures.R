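# Fixtures and independent oracles, built in code.

# Literal triple-loop implementation of the GDM, item by item and
# subject by subject; the reference against which the vectorized
# implementation is checked.
gdmBruteForce <- function(X) {
  n <- nrow(X); m <- ncol(X)
  sg <- function(a, b, j) sign(X[a, j] - X[b, j])
  tot <- function(a) {
    s <- 0
    for (j in 1:m) for (c in 1:n) s <- s + sg(a, c, j)^2
    s
  }
  D <- matrix(0, n, n)
  for (a in 1:n) for (b in 1:n) {
    if (a == b) next
    den <- 2 * sqrt(tot(a) * tot(b))
    d <- 0
    for (j in 1:m) {
      cs <- 0
      for (c in setdiff(1:n, c(a, b))) cs <- cs + sg(a, c, j) * sg(b, c, j)
      d <- d + 1 / (2 * m) - (-sg(a, b, j)^2 + cs) / den
    }
    D[a, b] <- d
  }
  D
}

randomCohort <- function(n, m, maxScore = 4L) {
  X <- matrix(sample(0:maxScore, n * m, replace = TRUE), n, m,
              dimnames = list(paste0("s", 1:n), paste0("i", 1:m)))
  OrdinalScoreMatrix(X, itemMax = rep(maxScore, m))
}

# Block-diagonal union of cliques (unit weights, unit diagonal).
cliqueNetwork <- function(sizes) {
  n <- sum(sizes)
  W <- matrix(0, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
  off <- 0
  for (s in sizes) {
    W[off + 1:s, off + 1:s] <- 1
    off <- off + s
  }
  W
}

# Reduced-size planted cohort for unit tests (the acceptance suite
# runs the full-size study conditions).
smallPlantedCohort <- function(seed, sizes = rep(15L, 5L), flipProb = 0.1) {
  generateCohort(syntheticCohortConfig(sizes = sizes, flipProb = flipProb,
                                       seed = seed))
}

# Binary volume set with one ellipsoid per subject, built directly.
sphereMask <- function(gridShape, center, radius) {
  q <- outer(outer((seq_len(gridShape[1]) - center[1])^2,
                   (seq_len(gridShape[2]) - center[2])^2, "+"),
             (seq_len(gridShape[3]) - center[3])^2, "+")
  array(as.integer(q <= radius^2), dim = gridShape)
}

adjRand <- function(a, b) mclust::adjustedRandIndex(a, b)
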