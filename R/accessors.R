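# Constructors, accessors and show methods.

#' Construct an OrdinalScoreMatrix
#'
#' @param scores integer-valued matrix (subjects x items) with rownames
#'   (subject ids) and colnames (item labels).
#' @param itemMax per-item maxima; inferred from the observed column
#'   maxima (at least 1) when omitted.
#' @param subjectData optional per-subject metadata data.frame.
#' @return an \linkS4class{OrdinalScoreMatrix}.
#' @examples
#' X <- matrix(c(0, 2, 1, 0, 3, 1), nrow = 3,
#'             dimnames = list(c("s1", "s2", "s3"), c("motor", "speech")))
#' OrdinalScoreMatrix(X, itemMax = c(motor = 4, speech = 2))
#' @export
OrdinalScoreMatrix <- function(scores, itemMax = NULL, subjectData = NULL) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("S", seq_len(nrow(scores)))
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("item", seq_len(ncol(scores)))
  if (is.null(itemMax)) {
    itemMax <- pmax(apply(scores, 2, max), 1)
  }
  itemMax <- as.integer(itemMax)
  names(itemMax) <- colnames(scores)
  if (is.null(subjectData))
    subjectData <- data.frame(row.names = rownames(scores))
  new("OrdinalScoreMatrix", scores = scores, itemMax = itemMax,
      subjectData = subjectData)
}

#' @rdname OrdinalScoreMatrix-class
#' @export
setMethod("scoreMatrix", "OrdinalScoreMatrix", function(x) x@scores)

#' @rdname OrdinalScoreMatrix-class
#' @export
setMethod("itemMax", "OrdinalScoreMatrix", function(x) x@itemMax)

#' @rdname OrdinalScoreMatrix-class
#' @export
setMethod("subjectIds", "OrdinalScoreMatrix", function(x) rownames(x@scores))

#' @rdname OrdinalScoreMatrix-class
#' @export
setMethod("itemNames", "OrdinalScoreMatrix", function(x) colnames(x@scores))

#' @rdname OrdinalScoreMatrix-class
#' @export
setMethod("nSubjects", "OrdinalScoreMatrix", function(x) nrow(x@scores))

#' @rdname OrdinalScoreMatrix-class
#' @export
setMethod("nItems", "OrdinalScoreMatrix", function(x) ncol(x@scores))

setMethod("show", "OrdinalScoreMatrix", function(object) {
  cat(sprintf("OrdinalScoreMatrix: %d subjects x %d items\n",
              nrow(object@scores), ncol(object@scores)))
  cat("item maxima:", paste(object@itemMax, collapse = " "), "\n")
  if (ncol(object@subjectData))
    cat("subjectData columns:",
        paste(names(object@subjectData), collapse = ", "), "\n")
})

#' @rdname DistanceMatrix-class
#' @export
setMethod("distances", "DistanceMatrix", function(x) x@D)

#' @rdname OrdinalScoreMatrix-class
#' @export
setMethod("subjectIds", "DistanceMatrix", function(x) rownames(x@D))

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix (GDM): %d subjects, range [%.3f, %.3f]\n",
              nrow(object@D), min(object@D[upper.tri(object@D)]),
              max(object@D[upper.tri(object@D)])))
})

#' @rdname SimilarityNetwork-class
#' @export
setMethod("adjacency", "SimilarityNetwork", function(x) x@W)

#' @rdname OrdinalScoreMatrix-class
#' @export
setMethod("subjectIds", "SimilarityNetwork", function(x) rownames(x@W))

setMethod("show", "SimilarityNetwork", function(object) {
  ut <- object@W[upper.tri(object@W)]
  cat(sprintf("SimilarityNetwork (GSM): %d nodes, %d edges, weights [%.3f, %.3f]\n",
              nrow(object@W), length(ut), min(ut), max(ut)))
})

#' @rdname ConsensusMatrix-class
#' @export
setMethod("consensus", "ConsensusMatrix", function(x) x@C)

#' @rdname ConsensusMatrix-class
#' @export
setMethod("nRuns", "ConsensusMatrix", function(x) x@nRuns)

#' @rdname ClusterAssignment-class
#' @export
setMethod("nClusters", "ConsensusMatrix", function(x) x@k)

setMethod("show", "ConsensusMatrix", function(object) {
  cat(sprintf("ConsensusMatrix: %d subjects, k = %d, N = %d runs\n",
              nrow(object@C), object@k, object@nRuns))
})

#' @rdname ClusterAssignment-class
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @rdname ClusterAssignment-class
#' @export
setMethod("nClusters", "ClusterAssignment", function(x) x@k)

setMethod("show", "ClusterAssignment", function(object) {
  tab <- table(object@labels)
  cat(sprintf("ClusterAssignment: %d subjects in %d clusters (sizes: %s)\n",
              length(object@labels), object@k, paste(tab, collapse = ", ")))
})

#' @rdname SpectralProfile-class
#' @export
setMethod("eigenvalues", "SpectralProfile", function(x) x@eigenvalues)

#' @rdname SpectralProfile-class
#' @export
setMethod("spectralGaps", "SpectralProfile", function(x) x@gaps)

setMethod("show", "SpectralProfile", function(object) {
  ev <- object@eigenvalues
  cat(sprintf("SpectralProfile: %d eigenvalues, lambda_1 = %.2e, max gap %.3f at k = %d\n",
              length(ev), ev[1], max(object@gaps), which.max(object@gaps)))
})

#' Construct a LesionVolumeSet
#'
#' @param masks list of binary 3D arrays (one per subject, identical
#'   dimensions), or a 4D array (x, y, z, subject).
#' @param affine 4x4 voxel-to-world transform; defaults to an identity
#'   transform with 1 mm^3 voxels.
#' @param subjectIds subject identifiers; taken from list/dimension
#'   names when omitted.
#' @return a \linkS4class{LesionVolumeSet}.
#' @export
LesionVolumeSet <- function(masks, affine = diag(4), subjectIds = NULL) {
  if (is.list(masks)) {
    dims <- unique(lapply(masks, dim))
    if (length(dims) != 1L)
      stop("all masks must share one grid shape")
    if (is.null(subjectIds)) subjectIds <- names(masks)
    masks <- array(unlist(masks, use.names = FALSE),
                   dim = c(dims[[1]], length(masks)))
  }
  if (is.null(subjectIds))
    subjectIds <- dimnames(masks)[[4]]
  if (is.null(subjectIds))
    subjectIds <- paste0("S", seq_len(dim(masks)[4]))
  storage.mode(masks) <- "integer"
  if (!all(masks %in% c(0L, 1L))) {
    warning("non-binary mask values binarized at > 0.5")
    masks <- array(as.integer(masks > 0.5), dim = dim(masks))
  }
  dimnames(masks) <- c(vector("list", 3), list(subjectIds))
  new("LesionVolumeSet", masks = masks, affine = affine)
}

#' @rdname LesionVolumeSet-class
#' @export
setMethod("lesionMasks", "LesionVolumeSet", function(x) x@masks)

#' @rdname LesionVolumeSet-class
#' @export
setMethod("voxelAffine", "LesionVolumeSet", function(x) x@affine)

#' @rdname LesionVolumeSet-class
#' @export
setMethod("gridShape", "LesionVolumeSet", function(x) dim(x@masks)[1:3])

#' @rdname OrdinalScoreMatrix-class
#' @export
setMethod("subjectIds", "LesionVolumeSet", function(x) dimnames(x@masks)[[4]])

#' @rdname OrdinalScoreMatrix-class
#' @export
setMethod("nSubjects", "LesionVolumeSet", function(x) dim(x@masks)[4])

setMethod("show", "LesionVolumeSet", function(object) {
  d <- dim(object@masks)
  cat(sprintf("LesionVolumeSet: %d subjects on a %d x %d x %d grid\n",
              d[4], d[1], d[2], d[3]))
})

setMethod("show", "VoxelTestResult", function(object) {
  cat(sprintf(
    "VoxelTestResult: cluster %d vs rest, %d voxels tested, %d significant (alpha = %g, B = %d)\n",
    object@clusterId, length(object@selectedVoxels),
    sum(object@significant), object@familyAlpha, object@nPermutations))
})

setMethod("show", "CorrelationNetwork", function(object) {
  cat(sprintf(
    "CorrelationNetwork: %d item pairs, %d significant at FDR %g (%d permutations)\n",
    nrow(object@edges), sum(object@edges$significant, na.rm = TRUE),
    object@alpha, object@nPermutations))
  if (length(object@excludedItems))
    cat("constant items excluded:",
        paste(object@excludedItems, collapse = ", "), "\n")
})

#' @rdname CorrelationNetwork-class
#' @param x a CorrelationNetwork.
#' @export
correlationEdges <- function(x) x@edges
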