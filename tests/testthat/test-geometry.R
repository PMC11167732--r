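test_that("Kabsch superposition recovers exact and rigid-equivalent fits", {
  set.seed(11)
  pts <- matrix(rnorm(15), 5, 3)
  fit <- kabschFit(pts, pts)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$transform@rotation, diag(3), tolerance = 1e-8)
  R <- cageflex:::rotationAboutAxis(c(1, 2, 3), 1.1)
  moved <- sweep(tcrossprod(pts, R), 2, c(-4, 2, 7))
  fit2 <- kabschFit(moved, pts)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-9)
  expect_equal(applyTransform(moved, fit2$transform), pts,
               tolerance = 1e-9)
  expect_error(kabschFit(pts[1:2, ], pts[1:2, ]), "at least 3")
  expect_error(kabschFit(pts, pts[1:4, ]), "mismatch")
  line <- cbind(1:4, 2 * (1:4), -1 * (1:4))
  expect_error(kabschFit(line, line + rnorm(12, sd = 1e-12)), "degenerate")
})

test_that("Kabsch matches the brute-force rotation-grid oracle", {
  set.seed(21)
  for (rep in 1:2) {
    n <- sample(4:6, 1)
    ref <- matrix(rnorm(3 * n, sd = 2), n, 3)
    mobile <- ref + matrix(rnorm(3 * n, sd = 0.3), n, 3)
    R <- cageflex:::rotationAboutAxis(rnorm(3), runif(1, 0, pi))
    mobile <- sweep(tcrossprod(mobile, R), 2, runif(3, -3, 3))
    fit <- kabschFit(mobile, ref)
    oracle <- bruteForceFitRMSD(mobile, ref)
    expect_lt(abs(fit$rmsd - oracle), 1e-3)
    expect_lte(fit$rmsd, oracle + 1e-9)  # optimal, never worse
  }
})

test_that("Kabsch agrees with an independent superposition implementation", {
  set.seed(31)
  ref <- matrix(rnorm(18, sd = 2), 6, 3)
  mobile <- ref + matrix(rnorm(18, sd = 0.4), 6, 3)
  fit <- kabschFit(mobile, ref)
  xyz_fit <- bio3d::fit.xyz(fixed = as.numeric(t(ref)),
                            mobile = as.numeric(t(mobile)),
                            fixed.inds = bio3d::atom2xyz(1:6),
                            mobile.inds = bio3d::atom2xyz(1:6))
  bio3d_rmsd <- sqrt(mean(colSums(
    (matrix(xyz_fit, 3) - t(ref))^2)))
  expect_equal(fit$rmsd, bio3d_rmsd, tolerance = 1e-6)
})

test_that("side-chain RMSD follows the anchor-fit-then-measure convention", {
  tmpl <- leanTemplate()
  spec <- tmpl@cageSpec
  closed <- stateStructure(tmpl, "closed")
  open1 <- stateStructure(tmpl, "open1")
  expect_equal(sidechainRMSD(closed, closed, spec), 0, tolerance = 1e-12)
  ## rigid motion of one input is removed by the anchor fit
  R <- cageflex:::rotationAboutAxis(c(0, 1, 1), 0.8)
  moved <- setCoords(open1, sweep(tcrossprod(coords(open1), R), 2, -3))
  expect_equal(sidechainRMSD(open1, moved, spec), 0, tolerance = 1e-9)
  expect_equal(sidechainRMSD(closed, moved, spec),
               sidechainRMSD(closed, open1, spec), tolerance = 1e-9)
  ## with identical anchors the metric is the closed-form per-atom RMS
  ## displacement between the state coordinate sets
  sel <- resolveSelection(closed, spec)
  disp <- coords(closed)[sel@sidechainIdx, ] -
          coords(open1)[sel@sidechainIdx, ]
  expect_equal(sidechainRMSD(closed, open1, spec),
               sqrt(mean(rowSums(disp^2))), tolerance = 1e-9)
  ## symmetry
  expect_equal(sidechainRMSD(closed, open1, spec),
               sidechainRMSD(open1, closed, spec), tolerance = 1e-9)
})

test_that("RMSD matrices are symmetric with zero diagonal and exact entries", {
  tmpl <- leanTemplate()
  spec <- tmpl@cageSpec
  sts <- lapply(c("closed", "open1", "open2"),
                function(s) stateStructure(tmpl, s))
  m <- rmsdMatrix(sts, spec)
  expect_equal(m@values, t(m@values))
  expect_equal(unname(diag(m@values)), rep(0, 3))
  expect_equal(m@values[1, 2], tmpl@designedGaps["closed", "open1"],
               tolerance = 1e-9)
  dup <- rmsdMatrix(list(sts[[1]], sts[[1]]), spec)
  expect_equal(max(abs(dup@values)), 0, tolerance = 1e-9)
  ## anchor-identical states obey the triangle-like bound
  g <- m@values
  expect_lte(g[1, 3], g[1, 2] + g[2, 3] + 1e-6)
})

test_that("atom pair distances are Euclidean and rigid-invariant", {
  expect_equal(atomPairDistance(rbind(c(0, 0, 0), c(3, 4, 0)), c(1, 2)), 5)
  expect_error(atomPairDistance(rbind(c(0, 0, 0)), c(1, 2)), "out of range")
  tmpl <- leanTemplate()
  st <- stateStructure(tmpl, "open1")
  sel <- resolveSelection(st, tmpl@cageSpec)
  d0 <- atomPairDistance(st, sel@keyPairIdx)
  R <- cageflex:::rotationAboutAxis(c(2, 1, 0), 2.2)
  st2 <- setCoords(st, sweep(tcrossprod(coords(st), R), 2, 5))
  expect_equal(atomPairDistance(st2, sel@keyPairIdx), d0,
               tolerance = 1e-9)
})

test_that("RMSF matches closed forms and Gaussian sampling theory", {
  tmpl <- leanTemplate()
  base <- tmpl@states$closed
  n <- nrow(base)
  still <- cageTrajectory(tmpl@topology, list(base, base, base))
  expect_equal(unname(rmsf(still, prealigned = TRUE)), rep(0, n))
  ## one atom oscillating +/- d along x
  osc1 <- base; osc2 <- base
  osc1[5, 1] <- base[5, 1] + 0.7
  osc2[5, 1] <- base[5, 1] - 0.7
  osc <- cageTrajectory(tmpl@topology, list(osc1, osc2))
  r <- unname(rmsf(osc, prealigned = TRUE))
  expect_equal(r[5], 0.7, tolerance = 1e-9)
  expect_equal(r[-5], rep(0, n - 1))
  expect_warning(rmsf(cageTrajectory(tmpl@topology, list(base)),
                      prealigned = TRUE), "single-frame")
  ## per-coordinate sigma noise -> per-atom RMSF of sigma * sqrt(3)
  sim <- simulateTrajectory(tmpl, c(closed = 5000), noiseSigma = 0.2,
                            rigidMotion = FALSE, seed = 5)
  rr <- rmsf(sim$trajectory, prealigned = TRUE)
  expect_equal(mean(rr), 0.2 * sqrt(3), tolerance = 0.05)
})

test_that("radial distribution normalizes to 1 for uniform probes", {
  set.seed(9)
  probes <- matrix(runif(3 * 10000, 0, 100), ncol = 3)
  g <- radialDistribution(matrix(c(50, 50, 50), 1), probes, dr = 2,
                          rMax = 45, boxVolume = 1e6)
  bulk <- g$g[g$r > 20 & g$r < 45]
  expect_lt(abs(mean(bulk) - 1), 0.1)
  ## all probes at one radius concentrate in that bin
  dirs <- cageflex:::fibonacciSphere(200) * 7.3
  g2 <- radialDistribution(matrix(0, 1, 3), dirs, dr = 0.5, rMax = 10)
  expect_equal(sum(g2$g > 0), 1)
  expect_equal(g2$r[g2$g > 0], 7.25)
  expect_error(radialDistribution(matrix(0, 1, 3), probes[0, ],
                                  dr = 0.1, rMax = 5), "empty")
})
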