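makeVols <- function(masks, affine = diag(4)) {
  LesionVolumeSet(masks, affine = affine)
}

test_that("density maps are within-cluster lesion frequencies", {
  g <- c(4, 4, 3)
  m1 <- sphereMask(g, c(2, 2, 2), 1.2)
  m2 <- sphereMask(g, c(3, 3, 2), 1.2)
  vols <- makeVols(list(a = m1, b = m2, c = m1))
  # singleton cluster: density equals the subject's mask
  dm <- densityMap(vols, c(1, 2, 2), 1)
  expect_equal(dm, m1 + 0)
  # shared voxels 1.0, symmetric-difference voxels 0.5
  dm2 <- densityMap(vols, c(1, 2, 2), 2)
  shared <- m2 == 1 & m1 == 1
  expect_true(all(dm2[shared] == 1))
  expect_true(all(dm2[xor(m1 == 1, m2 == 1)] == 0.5))
  expect_true(all(dm2 >= 0 & dm2 <= 1))
  expect_error(densityMap(vols, c(1, 2, 2), 9), "empty cluster")
})

test_that("voxel selection reproduces the count threshold and is label-free", {
  # 172 subjects on a tiny grid: voxel 1 lesioned 8 times, voxel 2 only 7
  masks <- array(0L, dim = c(2, 2, 1, 172))
  masks[1, 1, 1, 1:8] <- 1L
  masks[2, 1, 1, 1:7] <- 1L
  vols <- makeVols(masks)
  idx <- suppressMessages(selectVoxels(vols, 0.05))
  expect_identical(attr(idx, "threshold"), 8L)        # floor(0.05 * 172)
  expect_identical(as.integer(idx), 1L)
  # selection touches pooled counts only: no labels in the signature
  expect_false("labels" %in% names(formals(selectVoxels)))

  # threshold 0 is promoted to 1
  small <- makeVols(array(rep(c(1L, 0L), c(4, 4 * 3)), c(2, 2, 2, 2)))
  idx2 <- suppressMessages(selectVoxels(small, 0.05))
  expect_identical(attr(idx2, "threshold"), 1L)
  # nothing selected -> empty with a warning
  empty <- makeVols(array(0L, c(2, 2, 1, 3)))
  expect_warning(suppressMessages(selectVoxels(empty, 0.5)), "no voxel")
})

test_that("the pooled-variance proportion statistic matches direct evaluation", {
  # direct arithmetic of the printed formula, written out independently
  n <- 100; ni <- 20; vPos <- 30; viPos <- 12
  p1 <- viPos / ni
  p2 <- (vPos - viPos) / (n - ni)
  pp <- vPos / n
  tRef <- abs(p1 - p2) / sqrt(pp * (1 - pp) * (1 / ni + 1 / (n - ni)))
  expect_equal(proportionStatistic(12, 20, 30, 100), tRef, tolerance = 1e-14)
  expect_equal(tRef, 3.273268, tolerance = 1e-6)   # frozen value

  # equal group proportions give 0
  expect_equal(proportionStatistic(6, 20, 30, 100), 0)
  # swapping cluster and rest leaves the statistic unchanged
  expect_equal(proportionStatistic(12, 20, 30, 100),
               proportionStatistic(30 - 12, 80, 30, 100), tolerance = 1e-12)
  # degenerate pooled proportion: 0 with a warning, never NaN
  expect_warning(t0 <- proportionStatistic(20, 20, 100, 100), "pooled")
  expect_identical(t0, 0)
  expect_error(proportionStatistic(5, 0, 10, 10), "ni")
})

test_that("maxT adjusted p-values are monotone, bounded and deterministic", {
  set.seed(31)
  g <- c(6, 6, 4)
  n <- 24
  masks <- array(0L, dim = c(g, n))
  for (i in 1:n)
    masks[, , , i] <- sphereMask(g, c(sample(2:5, 1), sample(2:5, 1), 2), 1.5)
  labels <- rep(1:2, each = 12)
  # a voxel lesioned in all of cluster 1 and never elsewhere
  masks[6, 6, 4, ] <- c(rep(1L, 12), rep(0L, 12))
  vols <- makeVols(masks)
  idx <- suppressMessages(selectVoxels(vols, 0.1))
  B <- 199
  res <- permutationMaxT(vols, labels, 1, idx, B = B, familyAlpha = 0.05,
                         seed = 77)
  p <- res@pAdjusted
  expect_true(all(p > 0 & p <= 1))
  expect_gte(min(p), 1 / (B + 1))
  ord <- order(-res@tObs, seq_along(res@tObs))
  expect_true(all(diff(p[ord]) >= -1e-12))       # step-down monotonicity
  # the extreme voxel is the most significant
  extreme <- which(res@selectedVoxels == prod(g))  # linear index of [6, 6, 4]
  expect_equal(p[extreme], min(p))
  expect_true(res@significant[extreme])
  # pure function of (inputs, B, seed)
  res2 <- permutationMaxT(vols, labels, 1, idx, B = B, familyAlpha = 0.05,
                          seed = 77)
  expect_identical(res@pAdjusted, res2@pAdjusted)
  expect_error(permutationMaxT(vols, rep(1, n), 1, idx, B = 10),
               "whole cohort")
})

test_that("one-vs-rest splits the overall alpha and mirrors at k = 2", {
  set.seed(13)
  g <- c(5, 5, 3)
  masks <- array(rbinom(prod(g) * 20, 1, 0.25), dim = c(g, 20))
  vols <- makeVols(masks)
  labels <- rep(1:2, each = 10)
  res <- suppressMessages(
    oneVsRestAnalysis(vols, labels, overallAlpha = 0.05, B = 50, seed = 3))
  expect_equal(res$cluster1@familyAlpha, 0.025)
  expect_equal(res$cluster1@tObs, res$cluster2@tObs, tolerance = 1e-12)

  lab5 <- rep(1:5, each = 4)
  res5 <- suppressMessages(
    oneVsRestAnalysis(vols, lab5, overallAlpha = 0.05, B = 20, seed = 3))
  expect_equal(res5$cluster3@familyAlpha, 0.01)
  expect_length(res5, 5)
})

test_that("lesion volumes convert voxel counts through the affine", {
  masks <- array(0L, dim = c(4, 4, 4, 2))
  masks[, , , 1][1:10] <- 1L   # 10-voxel lesion, subject 2 lesion-free
  vols <- makeVols(masks)                        # 1 mm^3 voxels
  expect_equal(unname(lesionVolumes(vols)), c(0.01, 0))
  vols2 <- makeVols(masks, affine = diag(c(2, 2, 2, 1)))
  expect_equal(unname(lesionVolumes(vols2))[1], 0.08)
})

test_that("the volume comparison matches the rank-formula oracle", {
  masks <- array(0L, dim = c(4, 4, 2, 6))
  sizes <- c(1, 2, 3, 10, 11, 12)
  for (i in 1:6) masks[, , , i][seq_len(sizes[i])] <- 1L
  vols <- makeVols(masks)
  labels <- rep(1:2, each = 3)
  out <- lesionVolumeComparison(vols, labels, 1)
  # Kruskal-Wallis by direct rank arithmetic (no ties): ranks 1:6
  N <- 6
  H <- 12 / (N * (N + 1)) * (3 * mean(1:3)^2 + 3 * mean(4:6)^2) - 3 * (N + 1)
  expect_equal(out$H, H, tolerance = 1e-12)
  expect_equal(out$H, 27 / 7, tolerance = 1e-12)
  expect_equal(out$df, 1)

  # identical distributions: H = 0
  sizes2 <- c(1, 2, 3, 1, 2, 3)
  for (i in 1:6) { masks[, , , i] <- 0L; masks[, , , i][seq_len(sizes2[i])] <- 1L }
  out2 <- lesionVolumeComparison(makeVols(masks), labels, 1)
  expect_equal(out2$H, 0, tolerance = 1e-12)
  expect_error(lesionVolumeComparison(vols, rep(1, 6), 1), "whole cohort")
})

test_that("NIfTI masks round-trip through files and missing paths name the subject", {
  d <- withr::local_tempdir()
  g <- c(4, 5, 3)
  m <- sphereMask(g, c(2, 3, 2), 1.4)
  f1 <- file.path(d, "s1.nii.gz")
  writeVolume(m, diag(4), f1)
  vols <- readLesionMasks(c(s1 = f1))
  expect_equal(unname(lesionMasks(vols)[, , , 1]), m)
  expect_error(readLesionMasks(c(s1 = f1, ghost = file.path(d, "no.nii"))),
               "ghost")
})
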