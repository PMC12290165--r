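test_that("filterCohort applies the four inclusion rules on a toy cohort", {
  X <- rbind(
    zero   = c(0, 0, 0, 0),   # total score 0
    noscan = c(0, 2, 1, 0),   # no scan available
    vigil  = c(1, 1, 0, 2),   # vigilance > 0
    ok1    = c(0, 3, 0, 1),
    ok2    = c(0, 0, 2, 2))
  colnames(X) <- c("loc_vigilance", "motor", "sensory", "language")
  raw <- OrdinalScoreMatrix(X, itemMax = c(3, 4, 2, 3))
  scan <- c(zero = TRUE, noscan = FALSE, vigil = TRUE, ok1 = TRUE, ok2 = TRUE)

  out <- suppressMessages(filterCohort(raw, scan, "loc_vigilance"))
  expect_identical(subjectIds(out), c("ok1", "ok2"))
  expect_identical(itemNames(out), c("motor", "sensory", "language"))
  expect_equal(nItems(out), nItems(raw) - 1L)

  log <- attr(out, "dropLog")
  expect_setequal(log$subject, c("zero", "noscan", "vigil"))
  expect_match(log$reason[log$subject == "noscan"], "no scan")
  expect_match(log$reason[log$subject == "vigil"], "vigilance")
})

test_that("filtering is a no-op subject-wise when all subjects qualify", {
  X <- cbind(loc_vigilance = c(0, 0, 0), motor = c(1, 2, 3))
  rownames(X) <- paste0("s", 1:3)
  raw <- OrdinalScoreMatrix(X)
  out <- filterCohort(raw, rep(TRUE, 3), "loc_vigilance")
  expect_equal(nSubjects(out), 3L)
  expect_identical(itemNames(out), "motor")
})

test_that("degenerate and malformed inputs are rejected", {
  X <- cbind(loc_vigilance = c(0, 0), motor = c(0, 0))
  rownames(X) <- c("a", "b")
  raw <- OrdinalScoreMatrix(X, itemMax = c(3, 4))
  expect_error(filterCohort(raw, c(TRUE, TRUE)), "fewer than 2 subjects")
  expect_error(filterCohort(raw, TRUE), "length")
  Xna <- cbind(a = c(1, NA), b = c(0, 1))
  rownames(Xna) <- c("s1", "s2")
  expect_error(OrdinalScoreMatrix(Xna, itemMax = c(2, 2)), "missing")
})

test_that("filterCohort is idempotent and order-independent", {
  set.seed(42)
  for (rep in 1:5) {
    X <- matrix(sample(0:3, 8 * 4, replace = TRUE), 8, 4,
                dimnames = list(paste0("s", 1:8),
                                c("loc_vigilance", "m1", "m2", "m3")))
    raw <- OrdinalScoreMatrix(X, itemMax = rep(3, 4))
    scan <- stats::setNames(sample(c(TRUE, TRUE, TRUE, FALSE), 8, TRUE),
                            rownames(X))
    once <- try(suppressMessages(filterCohort(raw, scan, "loc_vigilance")),
                silent = TRUE)
    if (inherits(once, "try-error")) next
    twice <- suppressMessages(
      filterCohort(once, scan[subjectIds(once)], "loc_vigilance"))
    expect_identical(scoreMatrix(twice), scoreMatrix(once))

    # manual rule application in a different order gives the same subjects
    keep <- rownames(X)[X[, "loc_vigilance"] == 0]
    keep <- keep[rowSums(X[keep, , drop = FALSE]) > 0]
    keep <- keep[scan[keep]]
    expect_identical(subjectIds(once), keep)
  }
})

test_that("cooccurrence counts match hand enumeration and ignore severity", {
  X <- matrix(c(1, 0, 2, 2, 3, 0), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  os <- OrdinalScoreMatrix(X, itemMax = c(4, 4))
  co <- cooccurrenceCounts(os)
  expect_identical(co["a", "b"], 1L)
  expect_identical(diag(co), c(a = 2L, b = 2L))

  X2 <- X; X2[X2 > 0] <- 4   # severity change
  co2 <- cooccurrenceCounts(OrdinalScoreMatrix(X2, itemMax = c(4, 4)))
  expect_identical(co, co2)

  zero <- OrdinalScoreMatrix(matrix(0, 3, 2,
            dimnames = list(paste0("s", 1:3), c("a", "b"))),
            itemMax = c(2, 2))
  expect_true(all(cooccurrenceCounts(zero) == 0L))
})

test_that("spearman rho matches the rank-based oracle and its analytic cases", {
  X <- matrix(c(0, 1, 2, 2, 3, 4, 4, 3, 2), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("a", "b", "c")))
  os <- OrdinalScoreMatrix(X, itemMax = rep(4, 3))
  net <- spearmanNetwork(os, nPerm = 200, seed = 3)
  e <- correlationEdges(net)
  # independent route: stats::cor on the same columns
  for (r in seq_len(nrow(e))) {
    expect_equal(e$rho[r],
                 cor(X[, e$item1[r]], X[, e$item2[r]], method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_equal(e$rho[e$item1 == "a" & e$item2 == "b"], 1)   # same ranking
  expect_equal(e$rho[e$item1 == "a" & e$item2 == "c"], -1)  # reversed

  dup <- OrdinalScoreMatrix(cbind(a = c(0, 2, 1, 3), b = c(0, 2, 1, 3)),
                            itemMax = c(3, 3))
  edup <- correlationEdges(spearmanNetwork(dup, nPerm = 50, seed = 1))
  expect_equal(edup$rho, 1)
})

test_that("spearman permutation p-values respect the add-one bounds and the pair count", {
  set.seed(7)
  os <- randomCohort(10, 5)
  nPerm <- 99
  e <- correlationEdges(spearmanNetwork(os, nPerm = nPerm, seed = 5))
  expect_equal(nrow(e), 5 * 4 / 2)
  expect_true(all(e$p_raw >= 1 / (nPerm + 1) - 1e-12))
  expect_true(all(e$p_raw <= 1))
})

test_that("constant items are excluded from the FDR family with a warning", {
  X <- cbind(a = c(1, 1, 1, 1), b = c(0, 1, 2, 3), c = c(3, 1, 0, 2))
  rownames(X) <- paste0("s", 1:4)
  os <- OrdinalScoreMatrix(X, itemMax = rep(3, 3))
  expect_warning(net <- spearmanNetwork(os, nPerm = 50, seed = 2), "constant")
  e <- correlationEdges(net)
  expect_equal(nrow(e), 3)                      # all candidate pairs listed
  expect_true(all(is.na(e$rho[e$item1 == "a"])))
  expect_true(all(!is.na(e$p_adjusted[e$item1 == "b"])))
})

test_that("cluster profiles report ordinal min/median/max with the lower-midpoint median", {
  X <- rbind(s1 = c(0, 2), s2 = c(1, 2), s3 = c(4, 3), s4 = c(1, 0))
  colnames(X) <- c("a", "b")
  os <- OrdinalScoreMatrix(X, itemMax = c(4, 3))

  prof <- clusterProfileSummary(os, c(1, 1, 1, 2))
  expect_equal(unname(prof$cluster1[, "a"]), c(0, 1, 4))  # {0,1,4}
  # singleton cluster: min = median = max = the profile itself
  expect_equal(unname(prof$cluster2["min", ]), unname(X["s4", ]))
  expect_equal(prof$cluster2["min", ], prof$cluster2["max", ])

  # even group: median is the lower of the two central order statistics
  prof2 <- clusterProfileSummary(os, c(1, 1, 2, 2))
  expect_equal(unname(prof2$cluster1["median", "a"]), 0)  # {0,1} -> 0
  sortedMid <- function(v) unname(sort(v)[length(v) / 2])
  expect_equal(unname(prof2$cluster2["median", "a"]),
               sortedMid(X[3:4, "a"]))
  # no means or SDs anywhere in the summary
  expect_identical(rownames(prof$cluster1), c("min", "median", "max"))
})

test_that("a partition with an empty cluster fails validity", {
  expect_error(new("ClusterAssignment", labels = c(1L, 1L, 2L), k = 3L,
                   seedLedger = 1L), "nonempty")
})

test_that("score tables and metadata round-trip through CSV", {
  d <- withr::local_tempdir()
  f <- file.path(d, "scores.csv")
  write.csv(data.frame(subject_id = c("a", "b"), loc_vigilance = c(0, 1),
                       motor = c(2, 0)), f, row.names = FALSE)
  cfgf <- file.path(d, "cfg.yaml")
  writeLines(c("loc_item: loc_vigilance", "item_max:",
               "  loc_vigilance: 3", "  motor: 4"), cfgf)
  os <- readScores(f, cfgf)
  expect_identical(attr(os, "locItem"), "loc_vigilance")
  expect_identical(unname(itemMax(os)), c(3L, 4L))

  fm <- file.path(d, "meta.csv")
  write.csv(data.frame(subject_id = c("a", "b"), scan_available = c(1, 0)),
            fm, row.names = FALSE)
  expect_identical(readScanMetadata(fm), c(a = TRUE, b = FALSE))
})
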