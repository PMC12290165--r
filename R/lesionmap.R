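# Voxel-wise lesion analysis: density maps, label-free voxel selection,
# pooled-variance proportion statistic, Westfall-Young step-down maxT
# permutation correction, Bonferroni across one-vs-rest families, and
# the lesion-volume rank test.

.maskMatrix <- function(vols, voxels = NULL) {
  M <- lesionMasks(vols)
  dim(M) <- c(prod(dim(M)[1:3]), dim(M)[4])   # voxels x subjects
  if (!is.null(voxels)) M <- M[voxels, , drop = FALSE]
  M
}

.alignLabels <- function(vols, labels) {
  if (is(labels, "ClusterAssignment")) labels <- clusterLabels(labels)
  if (length(labels) != nSubjects(vols))
    stop("labels must be aligned with the subjects of the volume set")
  as.integer(labels)
}

#' Read binary lesion masks from NIfTI files
#'
#' @param paths named character vector (subject id -> NIfTI path) or a
#'   manifest data.frame with columns \code{subject_id} and \code{path}.
#' @return a \linkS4class{LesionVolumeSet} with the affine of the first
#'   volume. Non-binary inputs are binarized at > 0.5 with a warning.
#' @export
readLesionMasks <- function(paths) {
  if (is.data.frame(paths)) {
    p <- paths$path
    names(p) <- as.character(paths$subject_id)
    paths <- p
  }
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing mask file for subject(s): ",
         paste(names(paths)[missing], collapse = ", "))
  vols <- lapply(paths, RNifti::readNifti)
  affine <- structure(RNifti::xform(vols[[1]]), code = NULL)
  masks <- lapply(vols, function(v) array(as.numeric(v), dim = dim(v)))
  LesionVolumeSet(masks, affine = unclass(affine)[1:4, 1:4],
                  subjectIds = names(paths))
}

#' Write a 3D volume as NIfTI with a given affine
#'
#' @param vol 3D array.
#' @param affine 4x4 voxel-to-world transform.
#' @param file output path (.nii or .nii.gz).
#' @export
writeVolume <- function(vol, affine, file) {
  img <- RNifti::asNifti(vol)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Cluster lesion density map
#'
#' Voxel-wise mean of the binary masks of one cluster: each voxel holds
#' the within-cluster lesion frequency in [0, 1].
#'
#' @param vols a \linkS4class{LesionVolumeSet}.
#' @param labels a \linkS4class{ClusterAssignment} or integer vector.
#' @param clusterId cluster whose density map is computed.
#' @return 3D numeric array on the input grid.
#' @export
densityMap <- function(vols, labels, clusterId) {
  labels <- .alignLabels(vols, labels)
  members <- labels == clusterId
  if (!any(members)) stop("empty cluster: ", clusterId)
  M <- lesionMasks(vols)[, , , members, drop = FALSE]
  out <- apply(M, 1:3, mean)
  dimnames(out) <- NULL
  out
}

#' Label-free voxel selection by pooled lesion count
#'
#' Selects voxels lesioned in at least \code{floor(minFraction * n)}
#' subjects (a zero threshold is promoted to 1). With n = 172 and the
#' 5\% criterion this reproduces a count threshold of 8. Selection uses
#' pooled counts only -- cluster labels play no role -- so one shared
#' selection serves all one-vs-rest families.
#'
#' @param vols a \linkS4class{LesionVolumeSet}.
#' @param minFraction minimal fraction of subjects, in (0, 1).
#' @return integer vector of linear voxel indices (1-based, array
#'   order), with the count threshold attached as attribute
#'   \code{"threshold"}.
#' @export
selectVoxels <- function(vols, minFraction = 0.05) {
  if (minFraction <= 0 || minFraction >= 1)
    stop("minFraction must lie in (0, 1)")
  n <- nSubjects(vols)
  thr <- max(1L, as.integer(floor(minFraction * n)))
  counts <- rowSums(.maskMatrix(vols))
  idx <- which(counts >= thr)
  if (length(idx) == 0L)
    warning("no voxel reaches the selection threshold of ", thr)
  message(sprintf("selectVoxels: threshold %d of %d subjects, %d voxels selected",
                  thr, n, length(idx)))
  attr(idx, "threshold") <- thr
  idx
}

#' Pooled-variance two-proportion statistic
#'
#' The voxel statistic comparing the lesion frequency in cluster i with
#' the remaining patients:
#' \deqn{t_v = \frac{|v_i^+/n_i - (v^+ - v_i^+)/(n - n_i)|}{
#'   \sqrt{\frac{v^+}{n}(1 - \frac{v^+}{n})(\frac{1}{n_i} + \frac{1}{n - n_i})}}}
#' Vectorized over voxels. When the pooled proportion \code{vPos/n} is
#' 0 or 1 both group proportions coincide and the statistic is defined
#' as 0 (with a warning) rather than NaN.
#'
#' @param viPos lesion count(s) of the voxel within cluster i.
#' @param ni cluster size, \code{0 < ni < n}.
#' @param vPos pooled lesion count(s) of the voxel.
#' @param n total number of patients.
#' @return nonnegative statistic, same length as \code{viPos}.
#' @export
proportionStatistic <- function(viPos, ni, vPos, n) {
  if (ni <= 0 || ni >= n) stop("ni must satisfy 0 < ni < n")
  if (any(vPos > n) || any(viPos > pmin(vPos, ni)))
    stop("inconsistent counts")
  pPool <- vPos / n
  num <- abs(viPos / ni - (vPos - viPos) / (n - ni))
  den <- sqrt(pPool * (1 - pPool) * (1 / ni + 1 / (n - ni)))
  degenerate <- den == 0
  if (any(degenerate))
    warning("pooled proportion 0 or 1: statistic set to 0 for ",
            sum(degenerate), " voxel(s)")
  den[degenerate] <- 1
  out <- num / den              # den recycles over permutation columns
  if (is.matrix(out)) out[degenerate, ] <- 0 else out[degenerate] <- 0
  out
}

#' Permutation maxT test for one cluster family
#'
#' One-vs-rest voxel-wise test with Westfall-Young step-down maxT
#' adjustment: the cluster indicator is permuted B times; for each
#' permutation the statistic is recomputed at every selected voxel;
#' voxels are ordered by decreasing observed statistic (ties broken by
#' voxel index) and compared against successive maxima of the permuted
#' statistics over the not-yet-ordered tail; add-one p-values with
#' enforced monotonicity give FWER control at \code{familyAlpha}.
#'
#' @param vols a \linkS4class{LesionVolumeSet}.
#' @param labels a \linkS4class{ClusterAssignment} or integer vector.
#' @param clusterId the cluster tested against all remaining subjects.
#' @param selectedVoxels linear voxel indices from
#'   \code{\link{selectVoxels}}.
#' @param B number of permutations (the reference analysis used 5000).
#' @param familyAlpha per-family FWER level.
#' @param seed RNG seed for the permutations.
#' @return a \linkS4class{VoxelTestResult}.
#' @export
permutationMaxT <- function(vols, labels, clusterId, selectedVoxels,
                            B = 5000L, familyAlpha = 0.01, seed = 1L) {
  labels <- .alignLabels(vols, labels)
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  if (length(selectedVoxels) == 0L) stop("selectedVoxels must be nonempty")
  g <- as.numeric(labels == clusterId)
  n <- length(g)
  ni <- sum(g)
  if (ni == 0 || ni == n)
    stop("cluster ", clusterId, " is empty or equals the whole cohort")

  M <- .maskMatrix(vols, selectedVoxels)
  vPos <- rowSums(M)
  tObs <- suppressWarnings(
    proportionStatistic(as.numeric(M %*% g), ni, vPos, n))

  # step-down order: decreasing |t|, ties by voxel index
  ord <- order(-tObs, seq_along(tObs))
  V <- length(tObs)

  # permuted statistics, chunked over permutations; for each permutation
  # record the successive maxima over the tail of the step-down order
  seeds <- .deriveSeeds(seed, 1L)
  exceed <- numeric(V)          # counts of maxT_perm >= tObs along ord
  .withSeed(seeds[1], {
    done <- 0L
    while (done < B) {
      nb <- min(250L, B - done)
      G <- vapply(seq_len(nb), function(i) g[sample.int(n)], numeric(n))
      Tp <- suppressWarnings(
        proportionStatistic(M %*% G, ni, vPos, n))   # V x nb
      To <- Tp[ord, , drop = FALSE]
      # successive maxima from the bottom of the ordering upwards
      Um <- if (V == 1L) To else
        apply(To[V:1, , drop = FALSE], 2, cummax)[V:1, , drop = FALSE]
      exceed <- exceed + rowSums(Um >= tObs[ord] - 1e-12)
      done <- done + nb
    }
  })
  pOrd <- (1 + exceed) / (B + 1)
  pOrd <- cummax(pOrd)          # step-down monotonicity
  pAdj <- numeric(V)
  pAdj[ord] <- pOrd

  new("VoxelTestResult", clusterId = as.integer(clusterId),
      selectedVoxels = as.integer(selectedVoxels), tObs = tObs,
      pAdjusted = pAdj, significant = pAdj <= familyAlpha,
      familyAlpha = familyAlpha, nPermutations = B,
      gridDim = as.integer(gridShape(vols)), affine = voxelAffine(vols))
}

#' One-vs-rest voxel-wise analysis across all clusters
#'
#' Runs \code{\link{permutationMaxT}} once per cluster with a shared
#' label-free voxel selection and a Bonferroni-split per-family level
#' \code{familyAlpha = overallAlpha / k}, so the union of families is
#' FWER-controlled at \code{overallAlpha} (e.g. 0.05 over 5 clusters
#' gives 0.01 per family).
#'
#' @param vols a \linkS4class{LesionVolumeSet}.
#' @param labels a \linkS4class{ClusterAssignment} or integer vector
#'   with at least 2 clusters.
#' @param overallAlpha overall FWER level across families.
#' @param B permutations per family.
#' @param minFraction voxel selection fraction.
#' @param seed master seed; per-family seeds derive from it.
#' @return named list of \linkS4class{VoxelTestResult}, one per cluster.
#' @export
oneVsRestAnalysis <- function(vols, labels, overallAlpha = 0.05, B = 5000L,
                              minFraction = 0.05, seed = 1L) {
  labels <- .alignLabels(vols, labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("at least 2 clusters are required")
  voxels <- selectVoxels(vols, minFraction)
  famAlpha <- overallAlpha / length(ks)
  seeds <- .deriveSeeds(seed, length(ks))
  out <- lapply(seq_along(ks), function(i)
    permutationMaxT(vols, labels, ks[i], voxels, B = B,
                    familyAlpha = famAlpha, seed = seeds[i]))
  names(out) <- paste0("cluster", ks)
  out
}

#' Per-subject lesion volumes in milliliters
#'
#' Mask voxel count times the voxel volume from the affine
#' (|det| of the 3x3 block, in mm^3), divided by 1000.
#'
#' @param vols a \linkS4class{LesionVolumeSet}.
#' @return named numeric vector of volumes in mL.
#' @export
lesionVolumes <- function(vols) {
  voxVol <- abs(det(voxelAffine(vols)[1:3, 1:3]))
  out <- colSums(.maskMatrix(vols)) * voxVol / 1000
  names(out) <- subjectIds(vols)
  out
}

#' One-vs-rest lesion volume comparison (Kruskal-Wallis)
#'
#' Rank test (1 df) comparing the lesion volumes of one cluster with
#' all remaining subjects.
#'
#' @param vols a \linkS4class{LesionVolumeSet}.
#' @param labels a \linkS4class{ClusterAssignment} or integer vector.
#' @param clusterId the cluster compared with the rest.
#' @return list with \code{H} (chi-squared statistic), \code{df} and
#'   \code{p.value}.
#' @export
lesionVolumeComparison <- function(vols, labels, clusterId) {
  labels <- .alignLabels(vols, labels)
  members <- labels == clusterId
  if (!any(members) || all(members))
    stop("cluster must be nonempty and not the whole cohort")
  v <- lesionVolumes(vols)
  if (length(unique(v)) == 1L)
    warning("all lesion volumes are tied; the rank test is degenerate")
  kt <- stats::kruskal.test(v, factor(members))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}
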