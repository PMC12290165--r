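#' @rdname OrdinalScoreMatrix-class
#' @param x an object.
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname OrdinalScoreMatrix-class
#' @export
setGeneric("itemMax", function(x) standardGeneric("itemMax"))

#' @rdname OrdinalScoreMatrix-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname OrdinalScoreMatrix-class
#' @export
setGeneric("itemNames", function(x) standardGeneric("itemNames"))

#' @rdname OrdinalScoreMatrix-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname OrdinalScoreMatrix-class
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname SimilarityNetwork-class
#' @param x an object.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname DistanceMatrix-class
#' @param x an object.
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname ConsensusMatrix-class
#' @param x an object.
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))

#' @rdname ConsensusMatrix-class
#' @export
setGeneric("nRuns", function(x) standardGeneric("nRuns"))

#' @rdname ClusterAssignment-class
#' @param x an object.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterAssignment-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname SpectralProfile-class
#' @param x an object.
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname SpectralProfile-class
#' @export
setGeneric("spectralGaps", function(x) standardGeneric("spectralGaps"))

#' @rdname LesionVolumeSet-class
#' @param x an object.
#' @export
setGeneric("lesionMasks", function(x) standardGeneric("lesionMasks"))

#' @rdname LesionVolumeSet-class
#' @export
setGeneric("voxelAffine", function(x) standardGeneric("voxelAffine"))

#' @rdname LesionVolumeSet-class
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' Laplacian spectrum of a weighted graph
#'
#' Eigenvalues of the symmetric normalized Laplacian
#' \code{L_sym = I - D^(-1/2) A D^(-1/2)} of a nonnegative symmetric
#' adjacency matrix, in ascending order, with the consecutive eigengaps.
#'
#' @param A a \code{SimilarityNetwork}, \code{ConsensusMatrix} or
#'   nonnegative symmetric matrix.
#' @return a \linkS4class{SpectralProfile}.
#' @export
setGeneric("laplacianSpectrum", function(A) standardGeneric("laplacianSpectrum"))

#' @rdname spectralEmbedding
#' @export
setGeneric("spectralEmbedding", function(A, k) standardGeneric("spectralEmbedding"))
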