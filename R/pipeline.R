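# End-to-end orchestration: filter -> descriptive statistics -> GDM/GSM
# -> (optional) k selection -> RSC -> profiles, density maps and
# one-vs-rest voxel-wise tests, with artifacts and a provenance record.

#' Read a pipeline configuration from YAML or JSON
#'
#' @param file path to a YAML or JSON config.
#' @return a named list (see \code{\link{runPipeline}} for the fields).
#' @export
readPipelineConfig <- function(file) {
  if (grepl("\\.json$", file)) jsonlite::read_json(file, simplifyVector = TRUE)
  else yaml::read_yaml(file)
}

.writeMatrixCsv <- function(M, file) {
  df <- data.frame(subject_id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Sequences the whole workflow and writes every artifact under
#' \code{outDir}. The config is a named list (or a YAML/JSON path) with
#' fields:
#' \describe{
#'   \item{scores}{path to the scores CSV (see \code{\link{readScores}}),
#'     or an \code{OrdinalScoreMatrix}.}
#'   \item{scoresConfig}{optional sidecar config path for the scores.}
#'   \item{metadata}{optional scan-availability CSV
#'     (\code{\link{readScanMetadata}}).}
#'   \item{masks}{optional mask manifest CSV (columns subject_id, path)
#'     or a \code{LesionVolumeSet}.}
#'   \item{k}{cluster count, or \code{kRange} (vector) to select it.}
#'   \item{nRuns}{consensus runs N (default 500).}
#'   \item{permutations}{voxel-test permutations B (default 5000).}
#'   \item{overallAlpha}{overall FWER across families (default 0.05).}
#'   \item{minFraction}{voxel selection fraction (default 0.05).}
#'   \item{correlationPermutations}{Spearman permutations (default 1e4).}
#'   \item{fdrAlpha}{FDR level for the correlation network (default 0.05).}
#'   \item{seed}{master seed (default 1).}
#'   \item{outDir}{output directory.}
#' }
#' Subjects present in the score table but lacking a mask are treated
#' as having no available scan and are dropped at the filter stage; a
#' mask path that is listed but missing on disk aborts, naming the
#' subject.
#'
#' @param config named list or path to YAML/JSON.
#' @return (invisibly) the artifact manifest: a named list of file
#'   paths plus the selected k and labels.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  cfg <- utils::modifyList(list(
    nRuns = 500L, permutations = 5000L, overallAlpha = 0.05,
    minFraction = 0.05, correlationPermutations = 10000L,
    fdrAlpha = 0.05, seed = 1L, locItem = "loc_vigilance"), config)
  if (is.null(cfg$outDir)) stop("config must name an output directory (outDir)")
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(cfg$outDir, "run.log")
  logLine <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(msg); cat(msg, "\n", file = logFile, append = TRUE)
  }
  manifest <- list()

  raw <- .stage("load-scores", {
    if (is(cfg$scores, "OrdinalScoreMatrix")) cfg$scores
    else readScores(cfg$scores, cfg$scoresConfig)
  })
  if (!is.null(attr(raw, "locItem"))) cfg$locItem <- attr(raw, "locItem")

  vols <- NULL
  if (!is.null(cfg$masks)) {
    vols <- .stage("load-masks", {
      if (is(cfg$masks, "LesionVolumeSet")) cfg$masks
      else readLesionMasks(utils::read.csv(cfg$masks,
                                           stringsAsFactors = FALSE))
    })
  }

  scanAvail <- .stage("scan-availability", {
    sa <- if (!is.null(cfg$metadata)) readScanMetadata(cfg$metadata)
    else structure(rep(TRUE, nSubjects(raw)), names = subjectIds(raw))
    if (!is.null(vols)) {
      withMask <- subjectIds(raw) %in% subjectIds(vols)
      sa[subjectIds(raw)[!withMask]] <- FALSE
    }
    sa
  })

  scores <- .stage("filter", filterCohort(raw, scanAvail, cfg$locItem))
  logLine("filter: %d subjects, %d items retained",
          nSubjects(scores), nItems(scores))
  utils::write.csv(data.frame(subject_id = subjectIds(scores),
                              scoreMatrix(scores), check.names = FALSE),
                   manifest$scores <- file.path(cfg$outDir, "scores_filtered.csv"),
                   row.names = FALSE)
  dl <- attr(scores, "dropLog")
  if (!is.null(dl))
    utils::write.csv(dl, manifest$dropLog <-
                       file.path(cfg$outDir, "drop_log.csv"), row.names = FALSE)
  if (!is.null(vols))
    vols <- .stage("align-masks", {
      M <- lesionMasks(vols)[, , , subjectIds(scores), drop = FALSE]
      new("LesionVolumeSet", masks = M, affine = voxelAffine(vols))
    })

  .stage("descriptives", {
    co <- cooccurrenceCounts(scores)
    .writeMatrixCsv(co, manifest$cooccurrence <-
                      file.path(cfg$outDir, "cooccurrence.csv"))
    net <- spearmanNetwork(scores, nPerm = cfg$correlationPermutations,
                           alpha = cfg$fdrAlpha, seed = cfg$seed)
    utils::write.csv(correlationEdges(net), manifest$correlations <-
                       file.path(cfg$outDir, "correlation_network.csv"),
                     row.names = FALSE)
  })

  W <- .stage("similarity", {
    D <- gdmDistance(scores)
    .writeMatrixCsv(distances(D), manifest$distance <-
                      file.path(cfg$outDir, "gdm_distance.csv"))
    W <- gsmNetwork(D)
    .writeMatrixCsv(adjacency(W), manifest$similarity <-
                      file.path(cfg$outDir, "gsm_similarity.csv"))
    W
  })

  k <- cfg$k
  if (is.null(k)) {
    sel <- .stage("select-k", selectK(W, kRange = cfg$kRange,
                                      N = cfg$nRuns, seed = cfg$seed))
    utils::write.csv(sel$table, manifest$gapTable <-
                       file.path(cfg$outDir, "gap_table.csv"), row.names = FALSE)
    k <- sel$k
    logLine("select-k: k = %d", k)
  }

  part <- .stage("cluster", rscPartition(W, k, N = cfg$nRuns, seed = cfg$seed))
  labels <- part$assignment
  utils::write.csv(data.frame(subject_id = subjectIds(scores),
                              cluster = clusterLabels(labels)),
                   manifest$labels <- file.path(cfg$outDir, "labels.csv"),
                   row.names = FALSE)
  .writeMatrixCsv(consensus(part$consensus), manifest$consensus <-
                    file.path(cfg$outDir, "consensus.csv"))
  logLine("cluster: sizes %s",
          paste(table(clusterLabels(labels)), collapse = ", "))

  .stage("profiles", {
    prof <- clusterProfileSummary(scores, labels)
    tab <- do.call(rbind, lapply(names(prof), function(nm)
      data.frame(cluster = nm, statistic = rownames(prof[[nm]]),
                 prof[[nm]], check.names = FALSE)))
    utils::write.csv(tab, manifest$profiles <-
                       file.path(cfg$outDir, "cluster_profiles.csv"),
                     row.names = FALSE)
  })

  if (!is.null(vols)) {
    .stage("lesion-maps", {
      for (g in sort(unique(clusterLabels(labels)))) {
        dm <- densityMap(vols, labels, g)
        f <- file.path(cfg$outDir, sprintf("density_cluster%d.nii.gz", g))
        writeVolume(dm, voxelAffine(vols), f)
        manifest[[sprintf("density%d", g)]] <- f
      }
    })
    res <- .stage("voxel-tests",
      oneVsRestAnalysis(vols, labels, overallAlpha = cfg$overallAlpha,
                        B = cfg$permutations, minFraction = cfg$minFraction,
                        seed = cfg$seed))
    .stage("voxel-artifacts", {
      stats <- do.call(rbind, lapply(res, voxelStatsTable))
      utils::write.csv(stats, manifest$voxelStats <-
                         file.path(cfg$outDir, "voxel_stats.csv"),
                       row.names = FALSE)
      for (nm in names(res)) {
        f <- file.path(cfg$outDir, sprintf("significant_%s.nii.gz", nm))
        writeVolume(significanceMask(res[[nm]]), voxelAffine(vols), f)
        manifest[[paste0("sig_", nm)]] <- f
      }
      vol <- lesionVolumes(vols)
      utils::write.csv(data.frame(subject_id = names(vol), volume_ml = vol),
                       manifest$volumes <-
                         file.path(cfg$outDir, "lesion_volumes.csv"),
                       row.names = FALSE)
    })
  }

  prov <- list(package = "nihssRSC",
               version = as.character(utils::packageVersion("nihssRSC")),
               parameters = cfg[setdiff(names(cfg), c("scores", "masks"))],
               k = k, artifacts = manifest)
  jsonlite::write_json(prov, file.path(cfg$outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  manifest$provenance <- file.path(cfg$outDir, "provenance.json")
  logLine("done: %d artifacts", length(manifest))
  invisible(c(manifest, list(k = k, labels = clusterLabels(labels))))
}

#' Significance mask of a voxel test result
#'
#' @param x a \linkS4class{VoxelTestResult}.
#' @return binary 3D array on the test's grid.
#' @export
significanceMask <- function(x) {
  out <- array(0L, dim = x@gridDim)
  out[x@selectedVoxels[x@significant]] <- 1L
  out
}

#' Per-voxel statistics table
#'
#' Voxel index, world coordinates (via the affine), observed statistic
#' and maxT-adjusted p-value for every selected voxel of a family.
#'
#' @param x a \linkS4class{VoxelTestResult}.
#' @return data.frame.
#' @export
voxelStatsTable <- function(x) {
  ijk <- arrayInd(x@selectedVoxels, x@gridDim)
  world <- cbind(ijk - 1, 1) %*% t(x@affine)
  data.frame(cluster = x@clusterId, voxel = x@selectedVoxels,
             x = world[, 1], y = world[, 2], z = world[, 3],
             t = x@tObs, p_adjusted = x@pAdjusted,
             significant = x@significant)
}
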