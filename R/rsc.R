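# Repeated Spectral Clustering (RSC).
#
# One run = normalized-symmetric-Laplacian spectral clustering: embed
# the nodes with the k smallest eigenvectors of L_sym, row-normalize,
# k-means. N runs on W (embedding fixed, only the k-means centroid
# initialization re-randomized) are accumulated into the co-clustering
# consensus matrix C; C itself is then spectrally clustered with the
# same k. The number of clusters is chosen from the consensus eigengap
# profile (see selectK).

.asAdjacency <- function(A) {
  if (is(A, "SimilarityNetwork")) A <- adjacency(A)
  else if (is(A, "ConsensusMatrix")) A <- consensus(A)
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("A must be a square matrix, SimilarityNetwork or ConsensusMatrix")
  if (max(abs(A - t(A))) > 1e-9) stop("A must be symmetric")
  if (any(A < 0)) stop("A must be nonnegative")
  A
}

.lsym <- function(A) {
  d <- rowSums(A)
  if (any(d == 0)) {
    who <- if (is.null(rownames(A))) which(d == 0) else rownames(A)[d == 0]
    stop("zero-degree node(s): ", paste(who, collapse = ", "))
  }
  s <- 1 / sqrt(d)
  L <- diag(nrow(A)) - (s %o% s) * A
  (L + t(L)) / 2
}

#' @rdname laplacianSpectrum
#' @export
setMethod("laplacianSpectrum", "ANY", function(A) {
  A <- .asAdjacency(A)
  ev <- rev(eigen(.lsym(A), symmetric = TRUE, only.values = TRUE)$values)
  ev <- pmax(ev, 0)                       # numerical floor
  new("SpectralProfile", eigenvalues = ev, gaps = diff(ev))
})

#' @rdname laplacianSpectrum
#' @export
setMethod("laplacianSpectrum", "SimilarityNetwork",
          function(A) callNextMethod())

#' @rdname laplacianSpectrum
#' @export
setMethod("laplacianSpectrum", "ConsensusMatrix",
          function(A) callNextMethod())

#' Spectral embedding with the k smallest Laplacian eigenvectors
#'
#' Coordinates for the graph nodes in the space of the k eigenvectors
#' of L_sym with smallest eigenvalues, with rows normalized to unit
#' length (the normalized-symmetric spectral clustering convention).
#' Rows with zero norm are replaced by the uniform unit vector with a
#' warning.
#'
#' @param A a \code{SimilarityNetwork}, \code{ConsensusMatrix} or
#'   nonnegative symmetric matrix.
#' @param k embedding dimension, \code{2 <= k < n}.
#' @return n x k matrix of row-normalized coordinates.
#' @export
setMethod("spectralEmbedding", "ANY", function(A, k) {
  A <- .asAdjacency(A)
  n <- nrow(A)
  k <- as.integer(k)
  if (k < 2L || k >= n) stop("k must satisfy 2 <= k < n")
  e <- eigen(.lsym(A), symmetric = TRUE)
  U <- e$vectors[, n - seq_len(k) + 1L, drop = FALSE]   # k smallest
  nr <- sqrt(rowSums(U^2))
  if (any(nr == 0)) {
    warning("zero-norm embedding row(s) replaced by the uniform unit vector")
    U[nr == 0, ] <- 1 / sqrt(k)
    nr[nr == 0] <- 1
  }
  U <- U / nr
  rownames(U) <- rownames(A)
  U
})

# Single k-means run: Forgy initialization from k distinct data rows,
# Lloyd iterations to convergence; empty clusters trigger a fresh
# initialization (the run seed advances deterministically).
.kmeansRun <- function(U, k, seed) {
  .withSeed(seed, {
    for (attempt in 1:100) {
      ctr <- U[sample.int(nrow(U), k), , drop = FALSE]
      if (anyDuplicated(ctr)) next
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(U, centers = ctr, iter.max = 300L,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit) && all(fit$size > 0)) return(fit$cluster)
    }
    stop("k-means failed to produce k nonempty clusters in 100 initializations")
  })
}

#' Cluster a spectral embedding with k-means
#'
#' One k-means partition of the embedding rows (Lloyd, single random
#' initialization from k distinct rows; re-initialized if a cluster
#' empties). Labels are canonicalized by first appearance, so the
#' partition is invariant to input row order up to relabeling.
#'
#' @param U embedding coordinate matrix (rows = subjects).
#' @param k number of clusters (at least 2, at most the number of
#'   distinct rows).
#' @param seed RNG seed for the initialization.
#' @return a \linkS4class{ClusterAssignment}.
#' @export
clusterEmbedding <- function(U, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (nrow(unique(U)) < k)
    stop("fewer distinct embedding rows than clusters")
  lab <- .canonicalLabels(.kmeansRun(U, k, seed))
  names(lab) <- rownames(U)
  new("ClusterAssignment", labels = lab, k = k,
      seedLedger = as.integer(seed))
}

#' Accumulate a co-clustering consensus matrix over N runs
#'
#' The spectral embedding of W is computed once; N k-means runs with
#' independent centroid initializations (seeds derived deterministically
#' from \code{seed}) are accumulated: \code{C[a, b]} is the fraction of
#' runs in which a and b share a cluster.
#'
#' @param W a \linkS4class{SimilarityNetwork} (or adjacency matrix).
#' @param k number of clusters per run.
#' @param N number of runs (default 500 stabilizes the consensus on
#'   the bundled fixtures; ~10 runs are enough to gauge stability).
#' @param seed master seed; the N run seeds derive from it.
#' @return a \linkS4class{ConsensusMatrix}.
#' @export
accumulateConsensus <- function(W, k, N = 500L, seed = 1L) {
  A <- .asAdjacency(W)
  N <- as.integer(N)
  if (N < 1L) stop("N must be >= 1")
  U <- spectralEmbedding(A, k)
  seeds <- .deriveSeeds(seed, N)
  C <- matrix(0, nrow(A), nrow(A))
  for (i in seq_len(N)) {
    lab <- .kmeansRun(U, k, seeds[i])
    C <- C + outer(lab, lab, "==")
  }
  C <- C / N
  diag(C) <- 1
  dimnames(C) <- dimnames(A)
  new(Class = "ConsensusMatrix", C = C, nRuns = N, k = as.integer(k))
}

# Best-of-restarts k-means: nstart independent initializations (seeds
# derived from `seed`), keeping the partition with the lowest
# within-cluster sum of squares. Used for the final clustering of the
# consensus matrix, where the result should not depend on a single
# initialization.
.kmeansBest <- function(U, k, seed, nstart = 20L) {
  seeds <- .deriveSeeds(seed, nstart)
  best <- NULL
  bestSS <- Inf
  for (s in seeds) {
    lab <- .kmeansRun(U, k, s)
    ctr <- rowsum(U, lab) / as.vector(table(lab))
    ss <- sum((U - ctr[lab, , drop = FALSE])^2)
    if (ss < bestSS - 1e-12) {
      bestSS <- ss
      best <- lab
    }
  }
  best
}

#' Repeated Spectral Clustering partition
#'
#' Phase 1 accumulates the consensus matrix C from N spectral
#' clustering runs on W; phase 2 spectrally clusters C itself with the
#' same k, using best-of-20 k-means restarts by objective so the final
#' partition does not hinge on one initialization (with a sharp C all
#' restarts agree). The final labels come with the consensus matrix
#' for inspection. The whole procedure is a pure function of
#' \code{(W, k, N, seed)}.
#'
#' @inheritParams accumulateConsensus
#' @return list with elements \code{assignment}
#'   (\linkS4class{ClusterAssignment}) and \code{consensus}
#'   (\linkS4class{ConsensusMatrix}).
#' @export
rscPartition <- function(W, k, N = 500L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  seeds <- .deriveSeeds(seed, 2L)
  cons <- accumulateConsensus(W, k, N, seed = seeds[1])
  U <- spectralEmbedding(cons, k)
  lab <- .canonicalLabels(.kmeansBest(U, k, seeds[2]))
  names(lab) <- rownames(U)
  assign <- new("ClusterAssignment", labels = lab, k = k,
                seedLedger = as.integer(seeds))
  list(assignment = assign, consensus = cons)
}

#' Select the number of clusters from consensus eigengap profiles
#'
#' For every candidate k a consensus matrix C_k is accumulated and the
#' k-th eigengap \code{g_k = lambda_{k+1} - lambda_k} of its L_sym
#' spectrum is measured, alongside the same gap of W. A perfectly
#' stable k-block consensus is a 0/1 matrix with \code{g_k(C_k) = 1}
#' (maximal spectral evidence of k components); noise-driven splits
#' blur C_k and shrink that gap. Merging genuine clusters (k below the
#' true count) is itself a stable operation -- the coarse candidates
#' retain sharp consensus matrices almost by construction -- so
#' sharpness alone cannot discriminate, and the informative resolution
#' is the finest one that still carries strong evidence. The selected
#' k is therefore the \emph{largest} candidate with
#' \code{g_k(C_k) >= 1/2}, i.e. the finest resolution at which a
#' majority of the maximal spectral evidence for a k-component
#' structure survives the N-run averaging. If no candidate reaches
#' 1/2, the candidate with the largest consensus gap is returned (ties
#' toward smaller k). The gap table also reports the increase
#' \code{g_k(C_k) - g_k(W)} of each candidate over the similarity
#' network, and the drop \code{g_k(C_k) - g_{k+1}(C_{k+1})}, for
#' inspection.
#'
#' @inheritParams accumulateConsensus
#' @param kRange integer vector of candidate k in [2, n - 1].
#' @return list with \code{k} (selected) and \code{table}, a data.frame
#'   with columns \code{k}, \code{gapW}, \code{gapC}, \code{increase},
#'   \code{drop}.
#' @export
selectK <- function(W, kRange = 2:8, N = 500L, seed = 1L) {
  A <- .asAdjacency(W)
  n <- nrow(A)
  kRange <- sort(unique(as.integer(kRange)))
  if (length(kRange) == 0L) stop("kRange must not be empty")
  if (min(kRange) < 2L || max(kRange) > n - 1L)
    stop("kRange must lie within [2, n - 1]")
  evW <- eigenvalues(laplacianSpectrum(A))
  # one extra candidate so the drop column is defined at max(kRange)
  kAll <- unique(c(kRange, min(max(kRange) + 1L, n - 1L)))
  seeds <- .deriveSeeds(seed, length(kAll))
  gapC <- vapply(seq_along(kAll), function(i) {
    ck <- accumulateConsensus(A, kAll[i], N, seed = seeds[i])
    ev <- eigenvalues(laplacianSpectrum(ck))
    ev[kAll[i] + 1L] - ev[kAll[i]]
  }, numeric(1))
  names(gapC) <- kAll
  gapW <- evW[kRange + 1L] - evW[kRange]
  nextGap <- gapC[as.character(pmin(kRange + 1L, n - 1L))]
  tab <- data.frame(
    k = kRange,
    gapW = gapW,
    gapC = gapC[as.character(kRange)],
    increase = gapC[as.character(kRange)] - gapW,
    drop = gapC[as.character(kRange)] - nextGap,
    row.names = NULL)
  supported <- tab$gapC >= 0.5
  sel <- if (any(supported)) max(tab$k[supported])
         else tab$k[which.max(tab$gapC)]   # first max: ties -> smaller k
  list(k = sel, table = tab)
}
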