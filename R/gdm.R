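# General Distance Measure (GDM) and General Similarity Measure (GSM).
#
# For ordered subject pair (a, b) and item j, sigma_abj is the sign of
# x_aj - x_bj. The per-item distance is
#   d_abj = 1/(2m) - ( -sigma_abj^2 + sum_{c != a,b} sigma_acj sigma_bcj )
#           / ( 2 * sqrt( sum_jc sigma_acj^2 * sum_jc sigma_bcj^2 ) )
# and d_ab = sum_j d_abj. Because sigma_aaj = sigma_bbj = 0, the c-sum
# over c != a,b equals the unrestricted matrix product, which the
# vectorized form below exploits:
#   d_ab = 1/2 - (P_ab - A_ab) / (2 * sqrt(r_a * r_b))
# with P = sum_j S_j S_j', A_ab = #items on which a and b differ, and
# r_a = sum_b A_ab the total sign mass of subject a. The measure uses
# the whole cohort for every pairwise value: adding a subject changes
# existing distances.

#' Pairwise sign-difference structure
#'
#' The three-index array \code{sigma[a, b, j] = sign(x_aj - x_bj)} in
#' {-1, 0, 1} underlying the GDM; antisymmetric in (a, b), zero on the
#' diagonal.
#'
#' @param x an \linkS4class{OrdinalScoreMatrix}.
#' @return n x n x m array of signs with subject/item dimnames.
#' @export
signDifference <- function(x) {
  .assertScores(x)
  X <- scoreMatrix(x)
  n <- nrow(X); m <- ncol(X)
  sig <- array(0, dim = c(n, n, m),
               dimnames = list(rownames(X), rownames(X), colnames(X)))
  for (j in seq_len(m))
    sig[, , j] <- sign(outer(X[, j], X[, j], "-"))
  sig
}

#' General Distance Measure between all subject pairs
#'
#' Rank-sign dissimilarity for ordinal profiles: each pairwise distance
#' depends on the sign structure of the whole cohort, not only on the
#' two profiles compared. Identical profiles have distance 0; for a
#' two-subject cohort any difference gives distance 1. Self-distance is
#' defined as 0. Values are checked against [0, 1] (tolerance 1e-9)
#' and clipped.
#'
#' @param x an \linkS4class{OrdinalScoreMatrix} with n >= 2 subjects.
#' @return a \linkS4class{DistanceMatrix}.
#' @export
gdmDistance <- function(x) {
  .assertScores(x)
  X <- scoreMatrix(x)
  n <- nrow(X); m <- ncol(X)
  P <- matrix(0, n, n)
  A <- matrix(0, n, n)
  for (j in seq_len(m)) {
    S <- sign(outer(X[, j], X[, j], "-"))
    P <- P + tcrossprod(S)      # sum_c sigma_acj sigma_bcj
    A <- A + S * S              # sum over j of sigma_abj^2
  }
  r <- rowSums(A)               # sum_j sum_c sigma_acj^2
  if (any(r == 0))
    stop("degenerate cohort: subject(s) identical to every other subject ",
         "on every item: ", paste(rownames(X)[r == 0], collapse = ", "))
  D <- 0.5 - (P - A) / (2 * sqrt(outer(r, r)))
  diag(D) <- 0
  excess <- max(0, max(D - 1), max(-D))
  if (excess > 1e-9)
    warning(sprintf("distances outside [0, 1] by %.3g before clipping", excess))
  D <- pmin(pmax(D, 0), 1)
  D <- (D + t(D)) / 2
  dimnames(D) <- list(rownames(X), rownames(X))
  new("DistanceMatrix", D = D)
}

#' General Similarity Measure network
#'
#' Elementwise complement \code{s_ab = 1 - d_ab} of a GDM distance
#' matrix; the diagonal is forced to 1. The result is the weighted
#' adjacency matrix W of the patient similarity graph.
#'
#' @param D a \linkS4class{DistanceMatrix} (or plain symmetric matrix of
#'   distances in [0, 1]).
#' @return a \linkS4class{SimilarityNetwork}.
#' @export
gsmNetwork <- function(D) {
  if (is(D, "DistanceMatrix")) D <- distances(D)
  W <- 1 - D
  diag(W) <- 1
  new("SimilarityNetwork", W = W)
}

#' Normalized Manhattan baseline distance
#'
#' Simple per-pair baseline for comparison with the GDM: the Manhattan
#' (L1) distance between score profiles, scaled by the maximal possible
#' disagreement \code{sum(itemMax)} so values lie in [0, 1]. Unlike the
#' GDM it ignores item variability across the cohort and scales with
#' the magnitude of score differences.
#'
#' @param x an \linkS4class{OrdinalScoreMatrix}.
#' @return a \linkS4class{DistanceMatrix}.
#' @export
manhattanDistance <- function(x) {
  .assertScores(x)
  X <- scoreMatrix(x)
  D <- as.matrix(stats::dist(X, method = "manhattan")) / sum(itemMax(x))
  dimnames(D) <- list(rownames(X), rownames(X))
  new("DistanceMatrix", D = D)
}
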