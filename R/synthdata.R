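# Synthetic cohorts: ordinal score matrices with planted prototype
# structure plus companion binary lesion volumes with cluster-specific
# loci, so the whole pipeline is exercisable without patient data.

.defaultItems <- function() {
  # 14 NIHSS-style items (vigilance already removed), standard maxima
  items <- c("loc_questions", "loc_commands", "best_gaze", "visual",
             "facial_palsy", "motor_arm_left", "motor_arm_right",
             "motor_leg_left", "motor_leg_right", "limb_ataxia",
             "sensory", "best_language", "dysarthria", "inattention")
  mx <- c(2L, 2L, 2L, 3L, 3L, 4L, 4L, 4L, 4L, 2L, 2L, 3L, 2L, 2L)
  names(mx) <- items
  mx
}

.defaultPrototypes <- function() {
  mx <- .defaultItems()
  P <- matrix(0L, 5, length(mx), dimnames = list(
    c("left_motor", "visual_inattention", "right_motor",
      "lacunar_mild", "language"), names(mx)))
  # illustrative syndrome prototypes, not clinical claims: each
  # syndrome elevates its own item set so the five profiles are
  # mutually well separated in sign structure
  P["left_motor", c("motor_arm_left", "motor_leg_left", "facial_palsy",
                    "sensory")] <- c(4L, 3L, 2L, 1L)
  P["visual_inattention", c("visual", "inattention", "best_gaze",
                            "sensory")] <- c(3L, 2L, 2L, 1L)
  P["right_motor", c("motor_arm_right", "motor_leg_right", "facial_palsy",
                     "dysarthria")] <- c(4L, 3L, 2L, 2L)
  P["lacunar_mild", c("facial_palsy", "motor_arm_left", "motor_arm_right",
                      "dysarthria", "sensory", "limb_ataxia")] <-
    c(1L, 1L, 1L, 1L, 1L, 2L)
  P["language", c("best_language", "loc_questions", "loc_commands",
                  "dysarthria")] <- c(3L, 2L, 2L, 1L)
  P
}

.defaultLesionCenters <- function(gridShape) {
  # one locus per prototype, spread over the grid
  g <- gridShape
  rbind(
    left_motor = round(c(0.75, 0.50, 0.50) * g),   # right-hemisphere locus
    visual_inattention = round(c(0.50, 0.80, 0.40) * g),
    right_motor = round(c(0.25, 0.50, 0.50) * g),  # left-hemisphere locus
    lacunar_mild = round(c(0.50, 0.45, 0.45) * g),
    language = round(c(0.20, 0.40, 0.65) * g))
}

#' Configuration for a synthetic cohort
#'
#' Defaults emulate the target study design: 14 ordinal items with
#' NIHSS maxima in {2, 3, 4}, five syndrome prototypes (left motor,
#' visual/inattention, right motor, mild lacunar-like, language) with
#' 30 subjects each, +/-1 ordinal flip noise, and cluster-specific
#' ellipsoidal lesion loci on a small 20 x 24 x 20 grid with sparse
#' background lesion noise.
#'
#' @param kTrue planted cluster count.
#' @param sizes per-cluster subject counts.
#' @param prototypes kTrue x m integer matrix of prototype scores
#'   (colnames = item names), within \code{itemMax}.
#' @param itemMax named per-item maxima.
#' @param flipProb per-item probability of perturbing a score by one
#'   ordinal step (direction random, clipped to the item range).
#' @param gridShape 3D lesion grid.
#' @param lesionCenters kTrue x 3 matrix of cluster lesion centers
#'   (voxel coordinates).
#' @param lesionRadiusRange per-subject lesion radius bounds (voxels).
#' @param backgroundRate per-voxel probability of a spurious lesioned
#'   voxel.
#' @param seed RNG seed.
#' @return a \code{SyntheticCohortConfig} list.
#' @export
syntheticCohortConfig <- function(kTrue = 5L, sizes = rep(30L, kTrue),
                                  prototypes = NULL, itemMax = NULL,
                                  flipProb = 0.1,
                                  gridShape = c(20L, 24L, 20L),
                                  lesionCenters = NULL,
                                  lesionRadiusRange = c(2.5, 4.5),
                                  backgroundRate = 0.002, seed = 1L) {
  if (is.null(itemMax)) itemMax <- .defaultItems()
  if (is.null(prototypes)) {
    if (kTrue != 5L)
      stop("default prototypes exist only for kTrue = 5; supply prototypes")
    prototypes <- .defaultPrototypes()
  }
  if (is.null(lesionCenters)) lesionCenters <- .defaultLesionCenters(gridShape)
  cfg <- list(kTrue = as.integer(kTrue), sizes = as.integer(sizes),
              prototypes = prototypes, itemMax = itemMax,
              flipProb = flipProb, gridShape = as.integer(gridShape),
              lesionCenters = lesionCenters,
              lesionRadiusRange = lesionRadiusRange,
              backgroundRate = backgroundRate, seed = as.integer(seed))
  class(cfg) <- "SyntheticCohortConfig"
  validateCohortConfig(cfg)
  cfg
}

#' @rdname syntheticCohortConfig
#' @param config a \code{SyntheticCohortConfig}.
#' @export
validateCohortConfig <- function(config) {
  with(config, {
    if (length(sizes) != kTrue || any(sizes < 1L))
      stop("sizes must have kTrue entries, all >= 1")
    if (nrow(prototypes) != kTrue || ncol(prototypes) != length(itemMax))
      stop("prototypes must be kTrue x length(itemMax)")
    if (any(prototypes < 0) || any(sweep(prototypes, 2, itemMax, ">")))
      stop("prototypes must respect the item ranges")
    if (flipProb < 0 || flipProb >= 1) stop("flipProb must lie in [0, 1)")
    if (nrow(lesionCenters) != kTrue)
      stop("lesionCenters must have one row per cluster")
    if (backgroundRate < 0 || backgroundRate >= 1)
      stop("backgroundRate must lie in [0, 1)")
  })
  invisible(config)
}

# Ellipsoidal binary lesion around `center` with per-axis radii.
.ellipsoidMask <- function(gridShape, center, radii) {
  cx <- seq_len(gridShape[1]); cy <- seq_len(gridShape[2])
  cz <- seq_len(gridShape[3])
  dx2 <- ((cx - center[1]) / radii[1])^2
  dy2 <- ((cy - center[2]) / radii[2])^2
  dz2 <- ((cz - center[3]) / radii[3])^2
  q <- outer(outer(dx2, dy2, "+"), dz2, "+")
  array(as.integer(q <= 1), dim = gridShape)
}

#' Generate a synthetic cohort with planted structure
#'
#' Scores are the cluster prototype plus independent per-item +/-1
#' ordinal flips (clipped to the item range; a lattice step, not
#' rounded Gaussian noise). Lesions are ellipsoids at the cluster's
#' locus with per-subject center jitter and radius, plus Bernoulli
#' background voxels. Fully reproducible from the config seed.
#'
#' @param config a \code{\link{syntheticCohortConfig}}.
#' @return list with \code{scores} (\linkS4class{OrdinalScoreMatrix}),
#'   \code{volumes} (\linkS4class{LesionVolumeSet}) and \code{truth}
#'   (\linkS4class{ClusterAssignment} of planted labels).
#' @export
generateCohort <- function(config) {
  validateCohortConfig(config)
  .withSeed(config$seed, {
    mx <- config$itemMax
    m <- length(mx)
    labels <- rep(seq_len(config$kTrue), config$sizes)
    n <- length(labels)
    ids <- sprintf("SYN%03d", seq_len(n))

    X <- t(vapply(labels, function(g) {
      x <- as.numeric(config$prototypes[g, ])
      flip <- stats::runif(m) < config$flipProb
      x[flip] <- x[flip] + sample(c(-1, 1), sum(flip), replace = TRUE)
      pmin(pmax(x, 0), mx)
    }, numeric(m)))
    dimnames(X) <- list(ids, names(mx))

    g3 <- config$gridShape
    rr <- config$lesionRadiusRange
    masks <- array(0L, dim = c(g3, n))
    for (i in seq_len(n)) {
      ctr <- config$lesionCenters[labels[i], ] + stats::rnorm(3, sd = 1)
      ctr <- pmin(pmax(ctr, 2), g3 - 1)
      radii <- stats::runif(3, rr[1], rr[2])
      mk <- .ellipsoidMask(g3, ctr, radii)
      if (config$backgroundRate > 0) {
        bg <- stats::rbinom(prod(g3), 1L, config$backgroundRate)
        mk <- pmax(mk, array(bg, dim = g3))
      }
      masks[, , , i] <- mk
    }
    dimnames(masks) <- c(vector("list", 3), list(ids))

    truth <- new("ClusterAssignment",
                 labels = structure(as.integer(labels), names = ids),
                 k = config$kTrue, seedLedger = config$seed)
    list(scores = OrdinalScoreMatrix(X, itemMax = mx),
         volumes = new("LesionVolumeSet", masks = masks, affine = diag(4)),
         truth = truth)
  })
}

#' Generate a global-null cohort
#'
#' Scores and lesions are generated independently and without any
#' cluster structure: scores are uniform over each item's range, and
#' every subject (with probability \code{lesionRate}) receives one
#' spherical lesion whose center concentrates smoothly around the grid
#' center, so central voxels exceed the pooled-count selection
#' threshold while no label-related signal exists. Supports
#' family-wise error calibration of the voxel-wise test.
#'
#' @param n subjects.
#' @param m items.
#' @param itemMax per-item maxima (recycled).
#' @param gridShape 3D grid.
#' @param lesionRate probability that a subject carries a lesion;
#'   0 gives all-empty masks.
#' @param seed RNG seed.
#' @return list with \code{scores} and \code{volumes}.
#' @export
generateNullCohort <- function(n = 30L, m = 14L, itemMax = 3L,
                               gridShape = c(16L, 16L, 16L),
                               lesionRate = 0.9, seed = 1L) {
  .withSeed(seed, {
    mx <- as.integer(rep_len(itemMax, m))
    ids <- sprintf("NUL%03d", seq_len(n))
    X <- vapply(mx, function(L) sample(0:L, n, replace = TRUE), numeric(n))
    dimnames(X) <- list(ids, paste0("item", seq_len(m)))
    g3 <- as.integer(gridShape)
    masks <- array(0L, dim = c(g3, n))
    for (i in seq_len(n)) {
      if (stats::runif(1) < lesionRate) {
        ctr <- g3 / 2 + stats::rnorm(3, sd = g3 / 8)
        ctr <- pmin(pmax(ctr, 2), g3 - 1)
        radii <- stats::runif(3, 2, 4.5)
        masks[, , , i] <- .ellipsoidMask(g3, ctr, radii)
      }
    }
    dimnames(masks) <- c(vector("list", 3), list(ids))
    list(scores = OrdinalScoreMatrix(X, itemMax = structure(mx,
           names = colnames(X))),
         volumes = new("LesionVolumeSet", masks = masks, affine = diag(4)))
  })
}
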