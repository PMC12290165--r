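#' @import methods
NULL

.isSymmetricTol <- function(M, tol = 1e-9) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol
}

#' OrdinalScoreMatrix: patient-by-item ordinal scores
#'
#' Container for a cohort of subjects scored on a set of ordinal items
#' (NIHSS-style): integer scores \code{0..L_j} where \code{L_j} is the
#' per-item maximum. Subject identifiers are the rownames of the score
#' matrix, item labels the colnames. Optional per-subject metadata
#' (e.g. scan availability) travels in \code{subjectData}.
#'
#' @slot scores integer-valued matrix, subjects in rows, items in columns.
#' @slot itemMax named integer vector of per-item maxima.
#' @slot subjectData data.frame of per-subject metadata (may have 0 columns),
#'   rownames aligned with the score matrix.
#'
#' @export
setClass("OrdinalScoreMatrix",
  representation(scores = "matrix", itemMax = "integer",
                 subjectData = "data.frame"))

setValidity("OrdinalScoreMatrix", function(object) {
  X <- object@scores
  msg <- character()
  if (!is.numeric(X)) msg <- c(msg, "scores must be a numeric matrix")
  if (nrow(X) < 2L) msg <- c(msg, "at least 2 subjects are required")
  if (ncol(X) < 1L) msg <- c(msg, "at least 1 item is required")
  if (is.null(rownames(X)) || anyDuplicated(rownames(X)))
    msg <- c(msg, "subject ids (rownames) must be present and unique")
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)))
    msg <- c(msg, "item names (colnames) must be present and unique")
  if (anyNA(X))
    msg <- c(msg, "missing scores are not supported")
  else {
    if (any(X != round(X)) || any(X < 0))
      msg <- c(msg, "scores must be non-negative integers")
    if (length(object@itemMax) != ncol(X))
      msg <- c(msg, "itemMax length must equal the number of items")
    else if (any(sweep(X, 2, object@itemMax, ">")))
      msg <- c(msg, "scores exceed the per-item maxima")
  }
  if (nrow(object@subjectData) != nrow(X))
    msg <- c(msg, "subjectData rows must match the number of subjects")
  if (length(msg)) msg else TRUE
})

#' Pairwise GDM distance matrix
#'
#' Symmetric matrix of General Distance Measure values \code{d_ab} in
#' [0, 1] with zero diagonal (self-distance is 0 by convention).
#'
#' @slot D symmetric numeric matrix of pairwise distances.
#' @export
setClass("DistanceMatrix", representation(D = "matrix"))

setValidity("DistanceMatrix", function(object) {
  D <- object@D
  msg <- character()
  if (!.isSymmetricTol(D)) msg <- c(msg, "D must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) msg <- c(msg, "diagonal must be 0")
  if (any(D < -1e-9) || any(D > 1 + 1e-9))
    msg <- c(msg, "distances must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Patient similarity network
#'
#' Weighted adjacency matrix W of General Similarity Measure values
#' \code{s_ab = 1 - d_ab}; nodes are subjects, diagonal is 1.
#'
#' @slot W symmetric numeric matrix with entries in [0, 1] and unit diagonal.
#' @export
setClass("SimilarityNetwork", representation(W = "matrix"))

setValidity("SimilarityNetwork", function(object) {
  W <- object@W
  msg <- character()
  if (!.isSymmetricTol(W)) msg <- c(msg, "W must be symmetric")
  if (any(abs(diag(W) - 1) > 1e-9)) msg <- c(msg, "diagonal must be 1")
  if (any(W < -1e-9) || any(W > 1 + 1e-9))
    msg <- c(msg, "similarities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Co-clustering consensus matrix
#'
#' Entry (a, b) is the fraction of the N spectral-clustering runs in
#' which subjects a and b were assigned to the same cluster.
#'
#' @slot C symmetric matrix of co-clustering fractions, unit diagonal.
#' @slot nRuns number of accumulated runs N.
#' @slot k number of clusters used in the runs.
#' @export
setClass("ConsensusMatrix",
  representation(C = "matrix", nRuns = "integer", k = "integer"))

setValidity("ConsensusMatrix", function(object) {
  C <- object@C
  msg <- character()
  if (!.isSymmetricTol(C)) msg <- c(msg, "C must be symmetric")
  if (any(abs(diag(C) - 1) > 1e-12)) msg <- c(msg, "diagonal must be 1")
  if (any(C < 0) || any(C > 1)) msg <- c(msg, "entries must lie in [0, 1]")
  if (object@nRuns < 1L) msg <- c(msg, "nRuns must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Cluster assignment
#'
#' Hard partition of the subjects into k clusters, labels in 1..k.
#' \code{seedLedger} records the RNG seeds that produced the partition.
#'
#' @slot labels named integer vector of cluster labels in 1..k.
#' @slot k number of clusters.
#' @slot seedLedger integer vector of seeds used.
#' @export
setClass("ClusterAssignment",
  representation(labels = "integer", k = "integer", seedLedger = "integer"))

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (any(object@labels < 1L) || any(object@labels > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (!all(seq_len(object@k) %in% object@labels))
    msg <- c(msg, "every cluster must be nonempty")
  if (length(msg)) msg else TRUE
})

#' Laplacian spectral profile
#'
#' Ascending eigenvalues of the symmetric normalized Laplacian
#' L_sym = I - D^(-1/2) A D^(-1/2) and the consecutive gaps
#' \code{g_k = lambda_{k+1} - lambda_k}.
#'
#' @slot eigenvalues ascending numeric vector, floored at 0.
#' @slot gaps numeric vector of consecutive differences.
#' @export
setClass("SpectralProfile",
  representation(eigenvalues = "numeric", gaps = "numeric"))

setValidity("SpectralProfile", function(object) {
  ev <- object@eigenvalues
  msg <- character()
  if (is.unsorted(ev)) msg <- c(msg, "eigenvalues must be ascending")
  if (any(ev < 0) || any(ev > 2 + 1e-6))
    msg <- c(msg, "L_sym eigenvalues must lie in [0, 2]")
  if (length(object@gaps) != length(ev) - 1L)
    msg <- c(msg, "gaps length must be length(eigenvalues) - 1")
  if (length(msg)) msg else TRUE
})

#' Per-subject binary lesion volumes on a common grid
#'
#' Binary 3D masks for every subject, stored as a 4D array
#' (x, y, z, subject), all sharing one grid and voxel-to-world affine.
#'
#' @slot masks 4D 0/1 array; 4th dimension indexed by subject id.
#' @slot affine 4x4 voxel-to-world transform.
#' @export
setClass("LesionVolumeSet",
  representation(masks = "array", affine = "matrix"))

setValidity("LesionVolumeSet", function(object) {
  msg <- character()
  if (length(dim(object@masks)) != 4L)
    msg <- c(msg, "masks must be a 4D array (x, y, z, subject)")
  else {
    if (is.null(dimnames(object@masks)[[4]]))
      msg <- c(msg, "subject ids must be set on the 4th dimension")
    if (!all(object@masks %in% c(0, 1)))
      msg <- c(msg, "masks must be binary")
  }
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (length(msg)) msg else TRUE
})

#' Voxel-wise one-vs-rest test result
#'
#' Result of the permutation maxT procedure for one cluster family:
#' the selected voxels, the observed pooled-variance proportion
#' statistics, step-down maxT adjusted p-values and the significance
#' calls at the per-family alpha.
#'
#' @slot clusterId cluster tested against the rest.
#' @slot selectedVoxels linear voxel indices (1-based, array order).
#' @slot tObs observed statistic per selected voxel.
#' @slot pAdjusted maxT-adjusted p-value per selected voxel.
#' @slot significant logical per selected voxel.
#' @slot familyAlpha per-family FWER level.
#' @slot nPermutations number of label permutations B.
#' @slot gridDim grid shape (nx, ny, nz).
#' @slot affine voxel-to-world transform of the input volumes.
#' @export
setClass("VoxelTestResult",
  representation(clusterId = "integer", selectedVoxels = "integer",
                 tObs = "numeric", pAdjusted = "numeric",
                 significant = "logical", familyAlpha = "numeric",
                 nPermutations = "integer", gridDim = "integer",
                 affine = "matrix"))

setValidity("VoxelTestResult", function(object) {
  msg <- character()
  nv <- length(object@selectedVoxels)
  if (length(object@tObs) != nv || length(object@pAdjusted) != nv ||
      length(object@significant) != nv)
    msg <- c(msg, "tObs, pAdjusted and significant must match selectedVoxels")
  if (any(object@tObs < 0)) msg <- c(msg, "tObs must be nonnegative")
  if (nv > 0 && (any(object@pAdjusted <= 0) || any(object@pAdjusted > 1)))
    msg <- c(msg, "adjusted p-values must lie in (0, 1]")
  if (nv > 0 && !identical(object@significant,
                           object@pAdjusted <= object@familyAlpha))
    msg <- c(msg, "significant must equal pAdjusted <= familyAlpha")
  if (length(msg)) msg else TRUE
})

#' Item correlation network
#'
#' Spearman correlation network over item pairs with permutation
#' p-values and Benjamini-Hochberg FDR flags. All m(m-1)/2 candidate
#' pairs are listed; pairs involving a constant item carry NA and are
#' excluded from the FDR family.
#'
#' @slot edges data.frame with columns item1, item2, rho, p_raw,
#'   p_adjusted, significant.
#' @slot nPermutations permutations used per pair.
#' @slot alpha FDR level.
#' @slot excludedItems items with constant scores, excluded from the family.
#' @export
setClass("CorrelationNetwork",
  representation(edges = "data.frame", nPermutations = "integer",
                 alpha = "numeric", excludedItems = "character"))

setValidity("CorrelationNetwork", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("item1", "item2", "rho", "p_raw", "p_adjusted", "significant")
  if (!all(need %in% names(e)))
    msg <- c(msg, paste("edges must have columns:", paste(need, collapse = ", ")))
  else {
    ok <- !is.na(e$rho)
    if (any(abs(e$rho[ok]) > 1 + 1e-12))
      msg <- c(msg, "rho must lie in [-1, 1]")
    okp <- !is.na(e$p_raw)
    if (any(e$p_raw[okp] <= 0) || any(e$p_raw[okp] > 1))
      msg <- c(msg, "p-values must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})
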