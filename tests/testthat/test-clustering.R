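fdmFromMatrix <- function(d) {
  new("FrameDistanceMatrix", frameIndices = seq_len(nrow(d)),
      values = unname(as.matrix(d)))
}

test_that("frame distance matrices implement the prealigned side-chain metric", {
  tmpl <- leanTemplate()
  base <- tmpl@states$closed
  ## identical frames -> zero matrix
  traj <- cageTrajectory(tmpl@topology, list(base, base, base))
  fdm <- frameDistanceMatrix(traj, tmpl@cageSpec)
  expect_equal(max(abs(fdm@values)), 0, tolerance = 1e-9)
  ## the closed/open pair reproduces the designed inter-template RMSD,
  ## also under per-frame rigid motion
  sim <- simulateTrajectory(tmpl, c(closed = 1, open1 = 1),
                            noiseSigma = 0, rigidMotion = TRUE, seed = 4)
  fdm2 <- frameDistanceMatrix(sim$trajectory, tmpl@cageSpec)
  expect_equal(fdm2@values[1, 2], tmpl@designedGaps["closed", "open1"],
               tolerance = 1e-6)
  ## stride keeps every stride-th frame
  sim3 <- simulateTrajectory(tmpl, c(closed = 100), noiseSigma = 0.05,
                             seed = 5)
  fdm3 <- frameDistanceMatrix(sim3$trajectory, tmpl@cageSpec, stride = 10)
  expect_equal(dim(fdm3@values), c(10, 10))
  expect_equal(fdm3@frameIndices, seq(1L, 100L, by = 10L))
  expect_error(frameDistanceMatrix(
    cageTrajectory(tmpl@topology, list(base)), tmpl@cageSpec),
    "fewer than 2")
})

test_that("agglomerative cuts recover separated groups deterministically", {
  set.seed(14)
  pts <- c(rnorm(6, 0, 0.1), rnorm(4, 10, 0.1))
  d <- as.matrix(dist(pts))
  fdm <- fdmFromMatrix(d)
  res <- hierarchicalCluster(fdm, 2)
  expect_equal(res@labels, c(rep(0L, 6), rep(1L, 4)))  # 0 = most populated
  expect_equal(res@populationFraction, c(0.6, 0.4))
  expect_true(res@medoidFrame[1] %in% 1:6)
  ## k = n: every frame its own cluster, degenerate indices flagged
  res_n <- hierarchicalCluster(fdm, 10)
  expect_equal(sort(unique(res_n@labels)), 0:9)
  expect_true(is.na(res_n@indices["psf"]))
  expect_error(hierarchicalCluster(fdm, 11), "out of range")
  ## determinism: identical runs give identical labels
  expect_identical(hierarchicalCluster(fdm, 3)@labels,
                   hierarchicalCluster(fdm, 3)@labels)
})

test_that("agglomerative merges match the step-replay oracle on 8 frames", {
  d <- randomDistanceMatrix(8, dim = 3, seed = 8)
  fdm <- fdmFromMatrix(d)
  oracle <- oracleAverageLinkagePartitions(d)
  for (k in 2:7) {
    got <- hierarchicalCluster(fdm, k)@labels
    expect_equal(canonicalPartition(got), canonicalPartition(oracle[[k]]),
                 info = paste("k =", k))
  }
})

test_that("validity indices match a direct-formula recomputation", {
  for (seed in c(3, 17)) {
    d <- randomDistanceMatrix(7, dim = 2, seed = seed)
    labels <- cutree(hclust(as.dist(d), method = "average"), k = 3)
    got <- validityIndices(d, labels)
    want <- oracleValidityIndices(d, labels)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("validity indices honour their limiting cases", {
  ## two point-clusters with zero spread: dbi 0, ssr/sst 1
  d <- matrix(5, 4, 4); d[1:2, 1:2] <- 0; d[3:4, 3:4] <- 0
  idx <- validityIndices(d, c(1, 1, 2, 2))
  expect_equal(unname(idx["dbi"]), 0)
  expect_equal(unname(idx["ssrSst"]), 1)
  expect_equal(unname(idx["psf"]), Inf)  # SSE 0 with k < n
  ## one cluster: SSR = 0 by definition
  d2 <- randomDistanceMatrix(5, seed = 2)
  idx2 <- validityIndices(d2, rep(1, 5))
  expect_equal(unname(idx2["ssrSst"]), 0)
  ## zero total scatter flags everything undefined
  idx3 <- validityIndices(matrix(0, 3, 3), c(1, 1, 2))
  expect_true(all(is.na(idx3)))
})

test_that("the k sweep selects the true blob count under psf-max", {
  set.seed(6)
  pts <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
               matrix(rnorm(30, 6, 0.2), ncol = 2),
               cbind(rnorm(15, 0, 0.2), rnorm(15, 12, 0.2)))
  fdm <- fdmFromMatrix(as.matrix(dist(pts)))
  sw <- sweepK(fdm, 2, 10)
  expect_equal(sw@selectedK, 3L)
  expect_equal(sw@selectionRule, "psf-max")
  ## ssr/sst is within [0,1] and non-decreasing along the sweep
  ssr <- vapply(sw@results, function(r) r@indices["ssrSst"], numeric(1))
  expect_true(all(ssr >= 0 & ssr <= 1))
  expect_true(all(diff(ssr) >= -1e-9))
  ## dbi is non-negative
  dbi <- vapply(sw@results, function(r) r@indices["dbi"], numeric(1))
  expect_true(all(dbi >= 0))
  ## kMax clips to the frame count
  small <- fdmFromMatrix(as.matrix(dist(rnorm(5))))
  sw2 <- sweepK(small, 2, 20)
  expect_equal(vapply(sw2@results, function(r) r@k, integer(1)),
               2:5, ignore_attr = TRUE)
  ## manual rule returns the requested k regardless of indices
  expect_equal(sweepK(fdm, 2, 10, rule = "manual", manualK = 4)@selectedK,
               4L)
})

test_that("cluster summaries report fractions, descriptors and assignments", {
  tmpl <- leanTemplate()
  spec <- tmpl@cageSpec
  refs <- lapply(stateNames(tmpl), function(s) stateStructure(tmpl, s))
  lib <- libraryFromExemplars(refs, stateNames(tmpl), spec)
  ## single cluster of identical frames: fraction 1, means = frame values
  base <- tmpl@states$closed
  traj1 <- cageTrajectory(tmpl@topology, list(base, base, base))
  fdm1 <- frameDistanceMatrix(traj1, spec)
  res1 <- hierarchicalCluster(fdm1, 1)
  sumy1 <- clusterSummary(traj1, res1, spec, library = lib)
  expect_equal(sumy1$fraction, 1)
  expect_equal(sumy1$meanKeyDistance,
               unname(tmpl@keyDistances["closed"]), tolerance = 1e-9)
  expect_equal(sumy1$assignedState, "closed")
  expect_equal(sumy1$rmsd_closed, 0, tolerance = 1e-9)
  ## 70/30 two-state trajectory: fractions exact, medoids classified
  sim <- simulateTrajectory(tmpl, c(closed = 70, open1 = 30),
                            noiseSigma = 0.2, seed = 7)
  fdm <- frameDistanceMatrix(sim$trajectory, spec)
  res <- hierarchicalCluster(fdm, 2)
  sumy <- clusterSummary(sim$trajectory, res, spec, library = lib)
  expect_equal(sumy$fraction, c(0.7, 0.3))
  expect_equal(sumy$assignedState, c("closed", "open1"))
})
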