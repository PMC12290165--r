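test_that("the L_sym spectrum matches closed forms and counts components", {
  # complete graph K_n (no self loops): eigenvalues 0 and n/(n-1)
  n <- 6
  Kn <- matrix(1, n, n) - diag(n)
  ev <- eigenvalues(laplacianSpectrum(Kn))
  expect_equal(ev, c(0, rep(n / (n - 1), n - 1)), tolerance = 1e-10)

  # two disconnected cliques: exactly two (near) zero eigenvalues
  W <- cliqueNetwork(c(4, 5))
  ev2 <- eigenvalues(laplacianSpectrum(W))
  expect_lt(ev2[2], 1e-10)
  expect_gt(ev2[3], 0.1)

  # scaling the adjacency leaves the spectrum unchanged
  expect_equal(ev2, eigenvalues(laplacianSpectrum(3.7 * W)), tolerance = 1e-9)

  # zero-degree node is reported by name
  A <- diag(0, 3); A[1, 2] <- A[2, 1] <- 1
  dimnames(A) <- list(c("x", "y", "z"), c("x", "y", "z"))
  expect_error(laplacianSpectrum(A), "z")
})

test_that("the spectral embedding separates components and has unit row norms", {
  W <- cliqueNetwork(c(5, 5))
  U <- spectralEmbedding(W, 2)
  expect_equal(unname(sqrt(rowSums(U^2))), rep(1, 10), tolerance = 1e-9)
  # nodes of one clique collapse to one point, cliques to distinct points
  expect_lt(max(dist(U[1:5, ])), 1e-8)
  expect_lt(max(dist(U[6:10, ])), 1e-8)
  expect_gt(min(as.matrix(dist(U))[1:5, 6:10]), 0.5)
  expect_error(spectralEmbedding(W, 1), "k must")
  expect_error(spectralEmbedding(W, 10), "k must")
})

test_that("k-means on the embedding recovers separated clouds for any seed", {
  U <- rbind(matrix(rnorm(20, 0, .05), 10, 2),
             matrix(rnorm(20, 5, .05), 10, 2))
  truth <- rep(1:2, each = 10)
  for (seed in c(1, 7, 123)) {
    ca <- clusterEmbedding(U, 2, seed)
    expect_equal(adjRand(clusterLabels(ca), truth), 1)
  }
  # duplicated rows are co-assigned
  U2 <- U[rep(1:20, each = 2), ]
  ca2 <- clusterEmbedding(U2, 2, 3)
  lab <- clusterLabels(ca2)
  expect_true(all(lab[seq(1, 39, 2)] == lab[seq(2, 40, 2)]))
  # invariance to row order, up to relabeling
  set.seed(9)
  perm <- sample(20)
  ca3 <- clusterEmbedding(U[perm, ], 2, 42)
  expect_equal(adjRand(clusterLabels(ca3), truth[perm]), 1)
  # fewer distinct rows than clusters
  expect_error(clusterEmbedding(matrix(1, 5, 2), 3, 1), "distinct")
})

test_that("consensus accumulation yields valid co-clustering fractions", {
  W <- cliqueNetwork(c(4, 4))
  c1 <- accumulateConsensus(W, 2, N = 1, seed = 5)
  expect_true(all(consensus(c1) %in% c(0, 1)))   # single run: 0/1
  cN <- accumulateConsensus(W, 2, N = 25, seed = 5)
  C <- consensus(cN)
  expect_true(all(C >= 0 & C <= 1))
  expect_true(all(diag(C) == 1))
  expect_identical(C, t(C))
  # disconnected cliques: every run recovers the components exactly
  expect_true(all(C[1:4, 1:4] == 1) && all(C[1:4, 5:8] == 0))
})

test_that("RSC recovers planted structure and is a pure function of its seed", {
  sim <- smallPlantedCohort(seed = 4)
  W <- gsmNetwork(gdmDistance(sim$scores))
  p1 <- rscPartition(W, 5, N = 100, seed = 11)
  expect_gte(adjRand(clusterLabels(p1$assignment),
                     clusterLabels(sim$truth)), 0.9)
  # determinism
  p2 <- rscPartition(W, 5, N = 100, seed = 11)
  expect_identical(clusterLabels(p1$assignment), clusterLabels(p2$assignment))
  expect_identical(consensus(p1$consensus), consensus(p2$consensus))
  # scale invariance of the whole pipeline
  p3 <- rscPartition(0.4 * adjacency(W), 5, N = 100, seed = 11)
  expect_identical(clusterLabels(p1$assignment), clusterLabels(p3$assignment))
  expect_error(rscPartition(W, 1, N = 10, seed = 1), "k must")
})

test_that("consensus fractions vs counts is cosmetic for the final partition", {
  sim <- smallPlantedCohort(seed = 8)
  W <- gsmNetwork(gdmDistance(sim$scores))
  cons <- accumulateConsensus(W, 5, N = 50, seed = 2)
  C <- consensus(cons)
  U1 <- spectralEmbedding(C, 5)
  U2 <- spectralEmbedding(C * nRuns(cons), 5)   # counts instead of fractions
  expect_equal(abs(U1), abs(U2), tolerance = 1e-8)
})

test_that("consensus within-cluster co-clustering exceeds between-cluster", {
  for (seed in c(3, 14)) {
    sim <- smallPlantedCohort(seed = seed)
    W <- gsmNetwork(gdmDistance(sim$scores))
    C <- consensus(accumulateConsensus(W, 5, N = 100, seed = 21))
    tr <- clusterLabels(sim$truth)
    same <- outer(tr, tr, "==") & upper.tri(C)
    diff <- outer(tr, tr, "!=") & upper.tri(C)
    expect_gt(mean(C[same]), mean(C[diff]))
  }
})

test_that("selectK finds the component count of disconnected cliques", {
  W <- cliqueNetwork(c(5, 5, 5))
  ev <- eigenvalues(laplacianSpectrum(W))
  expect_lt(ev[3], 1e-10)
  expect_gt(ev[4], 0.5)
  sel <- suppressWarnings(selectK(W, 2:5, N = 100, seed = 1))
  expect_equal(sel$k, 3)
  expect_equal(sel$table$increase, sel$table$gapC - sel$table$gapW,
               tolerance = 1e-12)
  expect_error(selectK(W, integer(0)), "empty")
})

test_that("selectK recovers the planted count at the study cluster size", {
  sim <- generateCohort(syntheticCohortConfig(seed = 6))
  W <- gsmNetwork(gdmDistance(sim$scores))
  sel <- selectK(W, 2:7, N = 200, seed = 9)
  expect_equal(sel$k, 5)
  expect_true(all(sel$table$gapC >= 0 & sel$table$gapC <= 1 + 1e-9))
})
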