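# Cohort loading, filtering and descriptive statistics.

#' Read an ordinal score table from CSV
#'
#' Expects one row per subject, first column the subject id, one column
#' per item with integer scores. An optional sidecar config (YAML or
#' JSON) may name the vigilance item and the per-item maxima:
#' \preformatted{
#' loc_item: LOC_V
#' item_max:
#'   LOC_V: 3
#'   motor_arm_left: 4
#' }
#'
#' @param file path to the scores CSV.
#' @param configFile optional path to a YAML/JSON sidecar.
#' @return an \linkS4class{OrdinalScoreMatrix}; the vigilance item name
#'   (if configured) is attached as attribute \code{"locItem"}.
#' @examples
#' scores <- readScores(
#'   system.file("extdata", "example_scores.csv", package = "nihssRSC"),
#'   system.file("extdata", "example_scores.yaml", package = "nihssRSC"))
#' scans <- readScanMetadata(
#'   system.file("extdata", "example_metadata.csv", package = "nihssRSC"))
#' filterCohort(scores, scans, attr(scores, "locItem"))
#' @export
readScores <- function(file, configFile = NULL) {
  tab <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  X <- as.matrix(tab[, -1, drop = FALSE])
  rownames(X) <- ids
  itemMax <- NULL
  locItem <- NULL
  if (!is.null(configFile)) {
    cfg <- if (grepl("\\.json$", configFile))
      jsonlite::read_json(configFile, simplifyVector = TRUE)
    else yaml::read_yaml(configFile)
    if (!is.null(cfg$item_max))
      itemMax <- unlist(cfg$item_max)[colnames(X)]
    locItem <- cfg$loc_item
  }
  out <- OrdinalScoreMatrix(X, itemMax = itemMax)
  attr(out, "locItem") <- locItem
  out
}

#' Read per-subject scan availability metadata from CSV
#'
#' Expects columns \code{subject_id} and \code{scan_available} (0/1).
#'
#' @param file path to the metadata CSV.
#' @return named logical vector of scan availability.
#' @export
readScanMetadata <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  out <- as.logical(tab$scan_available)
  names(out) <- as.character(tab$subject_id)
  out
}

#' Filter a raw cohort to the analyzable subset
#'
#' Applies the cohort inclusion rules: subjects without an available
#' brain scan are dropped, subjects with total score 0 are dropped
#' (their lesions produced no measurable deficit), subjects scoring
#' above 0 on the vigilance item are dropped (remaining items cannot be
#' assessed in unconscious patients), and the vigilance item column is
#' removed. The rules commute, so the result does not depend on their
#' order. Per-subject drop reasons are attached as attribute
#' \code{"dropLog"} and summarized in a message.
#'
#' @param x raw \linkS4class{OrdinalScoreMatrix} including the vigilance
#'   item.
#' @param scanAvailable logical vector, one entry per subject (aligned
#'   with \code{subjectIds(x)}, or named by subject id).
#' @param locItem name of the vigilance item column; use \code{NULL} if
#'   the table has none (no subject drop, no column removal).
#' @return the filtered \linkS4class{OrdinalScoreMatrix}.
#' @export
filterCohort <- function(x, scanAvailable = NULL, locItem = "loc_vigilance") {
  .assertScores(x)
  X <- scoreMatrix(x)
  n <- nrow(X)
  if (is.null(scanAvailable)) scanAvailable <- rep(TRUE, n)
  if (!is.null(names(scanAvailable))) {
    if (!all(rownames(X) %in% names(scanAvailable)))
      stop("scanAvailable is missing entries for some subjects")
    scanAvailable <- scanAvailable[rownames(X)]
  }
  if (length(scanAvailable) != n)
    stop("scanAvailable length must match the number of subjects")
  if (anyNA(scanAvailable))
    stop("scanAvailable must not contain missing values")

  if (!is.null(locItem) && !locItem %in% colnames(X))
    locItem <- NULL
  dropScan <- !scanAvailable
  dropZero <- rowSums(X) == 0
  dropLoc <- if (is.null(locItem)) rep(FALSE, n) else X[, locItem] > 0
  drop <- dropScan | dropZero | dropLoc

  reason <- vapply(seq_len(n), function(i) {
    paste(c("no scan", "total score 0", "vigilance > 0")[
      c(dropScan[i], dropZero[i], dropLoc[i])], collapse = "; ")
  }, character(1))
  dropLog <- data.frame(subject = rownames(X)[drop],
                        reason = reason[drop], stringsAsFactors = FALSE)

  keepItems <- setdiff(colnames(X), locItem)
  if (sum(!drop) < 2L)
    stop("fewer than 2 subjects remain after filtering (",
         sum(!drop), " retained)")
  out <- OrdinalScoreMatrix(X[!drop, keepItems, drop = FALSE],
                            itemMax = itemMax(x)[keepItems],
                            subjectData = x@subjectData[!drop, , drop = FALSE])
  if (nrow(dropLog))
    message(sprintf("filterCohort: dropped %d of %d subjects", nrow(dropLog), n))
  attr(out, "dropLog") <- dropLog
  out
}

#' Deficit co-occurrence counts
#'
#' Entry (i, j) counts the subjects exhibiting both deficits i and j
#' (score > 0 on both items), irrespective of severity; the diagonal
#' holds single-deficit occurrence counts.
#'
#' @param x an \linkS4class{OrdinalScoreMatrix}.
#' @return symmetric m x m integer matrix.
#' @export
cooccurrenceCounts <- function(x) {
  .assertScores(x)
  B <- scoreMatrix(x) > 0
  M <- crossprod(B)
  storage.mode(M) <- "integer"
  M
}

#' Spearman correlation network with permutation p-values
#'
#' Spearman's rho (mid-ranks for ties) for every item pair, with
#' two-sided permutation p-values obtained by independently permuting
#' one column per pair, under the add-one convention
#' \code{p = (1 + #(|rho_perm| >= |rho_obs|)) / (nPerm + 1)}, followed
#' by Benjamini-Hochberg FDR flags at \code{alpha}. Constant items
#' yield undefined rho; their pairs are reported with NA and excluded
#' from the FDR family (with a warning) rather than diluting the
#' correction.
#'
#' @param x an \linkS4class{OrdinalScoreMatrix} with at least 3 subjects.
#' @param nPerm number of permutations per pair (the reference analysis
#'   used 1e4).
#' @param alpha FDR level.
#' @param seed RNG seed for the permutations.
#' @return a \linkS4class{CorrelationNetwork}.
#' @export
spearmanNetwork <- function(x, nPerm = 10000L, alpha = 0.05, seed = 1L) {
  .assertScores(x)
  X <- scoreMatrix(x)
  n <- nrow(X); m <- ncol(X)
  if (n < 3L) stop("at least 3 subjects are required")
  if (nPerm < 1L) stop("nPerm must be >= 1")

  R <- apply(X, 2, rank)                      # mid-ranks
  sds <- apply(R, 2, stats::sd)
  constant <- sds == 0
  if (any(constant))
    warning("constant items excluded from the FDR family: ",
            paste(colnames(X)[constant], collapse = ", "))
  Z <- scale(R)                               # rho = crossprod(Z)/(n-1)

  pairs <- utils::combn(m, 2)
  nPairs <- ncol(pairs)
  rho <- p_raw <- rep(NA_real_, nPairs)
  seeds <- .deriveSeeds(seed, nPairs)
  for (p in seq_len(nPairs)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    if (constant[i] || constant[j]) next
    zi <- Z[, i]; zj <- Z[, j]
    robs <- sum(zi * zj) / (n - 1)
    rho[p] <- robs
    perm <- .withSeed(seeds[p], {
      idx <- replicate(nPerm, sample.int(n))
      colSums(zi * matrix(zj[idx], n, nPerm)) / (n - 1)
    })
    p_raw[p] <- (1 + sum(abs(perm) >= abs(robs) - 1e-12)) / (nPerm + 1)
  }
  p_adj <- rep(NA_real_, nPairs)
  fam <- !is.na(p_raw)
  p_adj[fam] <- stats::p.adjust(p_raw[fam], method = "BH")
  edges <- data.frame(
    item1 = colnames(X)[pairs[1, ]], item2 = colnames(X)[pairs[2, ]],
    rho = rho, p_raw = p_raw, p_adjusted = p_adj,
    significant = !is.na(p_adj) & p_adj < alpha,
    stringsAsFactors = FALSE)
  edges$significant[!fam] <- NA
  new("CorrelationNetwork", edges = edges, nPermutations = as.integer(nPerm),
      alpha = alpha, excludedItems = colnames(X)[constant])
}

# Ordinal median: lower midpoint of the two central order statistics
# for even group sizes, so the summary stays on the ordinal scale.
.ordinalMedian <- function(v) {
  s <- sort(v)
  s[ceiling(length(s) / 2)]
}

#' Per-cluster item profile summaries
#'
#' For each cluster and item, the minimum, median and maximum score
#' (the radar-chart summaries). Means and standard deviations are
#' deliberately not computed: the scale is ordinal. The median for
#' even-sized clusters is the lower of the two central order
#' statistics, keeping it on the ordinal lattice.
#'
#' @param x an \linkS4class{OrdinalScoreMatrix}.
#' @param labels a \linkS4class{ClusterAssignment} or integer vector
#'   aligned with the subjects.
#' @return named list (one element per cluster) of 3 x m matrices with
#'   rows \code{min}, \code{median}, \code{max}.
#' @export
clusterProfileSummary <- function(x, labels) {
  .assertScores(x)
  if (is(labels, "ClusterAssignment")) labels <- clusterLabels(labels)
  X <- scoreMatrix(x)
  if (length(labels) != nrow(X))
    stop("labels must be aligned with the subjects")
  out <- lapply(sort(unique(labels)), function(g) {
    Xi <- X[labels == g, , drop = FALSE]
    if (nrow(Xi) == 0L) stop("empty cluster: ", g)
    rbind(min = apply(Xi, 2, min),
          median = apply(Xi, 2, .ordinalMedian),
          max = apply(Xi, 2, max))
  })
  names(out) <- paste0("cluster", sort(unique(labels)))
  out
}
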