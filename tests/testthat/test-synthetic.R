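test_that("templates are deterministic and self-consistent", {
  t1 <- makeTemplate(seed = 3, scaffold = FALSE, verifyVolume = FALSE)
  t2 <- makeTemplate(seed = 3, scaffold = FALSE, verifyVolume = FALSE)
  expect_identical(t1@states, t2@states)
  expect_identical(coords(t1@topology), coords(t2@topology))
  ## stored designed gaps equal a fresh recomputation with the metric
  spec <- t1@cageSpec
  sn <- stateNames(t1)
  for (i in seq_along(sn)) for (j in seq_along(sn)) if (i < j) {
    got <- sidechainRMSD(stateStructure(t1, sn[i]),
                         stateStructure(t1, sn[j]), spec)
    expect_equal(got, t1@designedGaps[sn[i], sn[j]], tolerance = 1e-9)
  }
  ## all designed gaps respect the template invariant
  expect_true(all(t1@designedGaps[upper.tri(t1@designedGaps)] >= 2.0))
  ## key distances are exactly the designed values, and closed differs
  ## from each open state by the designed contrast
  sel <- resolveSelection(t1@topology, spec)
  for (s in sn)
    expect_equal(atomPairDistance(stateStructure(t1, s), sel@keyPairIdx),
                 unname(t1@keyDistances[s]), tolerance = 1e-9)
  expect_equal(unname(t1@keyDistances[c("closed", "open1", "open2")]),
               c(6.0, 9.5, 8.9))
  expect_true(all(abs(t1@keyDistances[c("open1", "open2")] -
                      t1@keyDistances["closed"]) >= 2.5))
  ## anchors (and all backbone atoms) are identical across states
  a <- atomTable(t1@topology)
  bb <- which(a$name %in% c("N", "CA", "C", "O"))
  expect_equal(t1@states$closed[bb, ], t1@states$open1[bb, ])
})

test_that("simulated trajectories honour noise, rigid motion and labels", {
  tmpl <- leanTemplate()
  ## sigma 0, no rigid motion: frames equal the state coordinates
  sim0 <- simulateTrajectory(tmpl, c(open2 = 3), noiseSigma = 0,
                             rigidMotion = FALSE, seed = 1)
  expect_equal(frameCoords(sim0$trajectory, 2),
               unname(tmpl@states$open2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sim0$labels, rep("open2", 3))
  ## sigma 0 with rigid motion: anchor fit removes it exactly
  simr <- simulateTrajectory(tmpl, c(open1 = 4), noiseSigma = 0,
                             rigidMotion = TRUE, seed = 2)
  ref <- stateStructure(tmpl, "open1")
  for (f in 1:4) {
    fr <- setCoords(tmpl@topology, frameCoords(simr$trajectory, f))
    expect_equal(sidechainRMSD(fr, ref, tmpl@cageSpec), 0,
                 tolerance = 1e-8)
  }
  ## identical seeds give identical trajectories
  s1 <- simulateTrajectory(tmpl, c(closed = 5, open1 = 5), seed = 9)
  s2 <- simulateTrajectory(tmpl, c(closed = 5, open1 = 5), seed = 9)
  expect_identical(coords(s1$trajectory), coords(s2$trajectory))
  expect_error(simulateTrajectory(tmpl, c(unknown = 5)), "unknown state")
  ## interpolation mode inserts labelled transition frames
  si <- simulateTrajectory(tmpl, c(closed = 3, open1 = 3), noiseSigma = 0,
                           rigidMotion = FALSE, seed = 1,
                           transitionFrames = 2)
  expect_equal(nFrames(si$trajectory), 8)
  expect_equal(si$labels, c("closed", "closed", "closed", "closed",
                            "open1", "open1", "open1", "open1"))
})

test_that("noisy frames classify to their generating states", {
  tmpl <- leanTemplate()
  refs <- lapply(stateNames(tmpl), function(s) stateStructure(tmpl, s))
  lib <- libraryFromExemplars(refs, stateNames(tmpl), tmpl@cageSpec)
  ## noise-free state coordinates classify exactly
  for (s in stateNames(tmpl))
    expect_equal(classifyConformer(stateStructure(tmpl, s), lib)@label, s)
  ## noisy frames (sigma 0.3) classify correctly in >= 99 percent of frames
  seg <- c(closed = 25, open1 = 25, open2 = 25, collapsed = 25)
  sim <- simulateTrajectory(tmpl, seg, noiseSigma = 0.3, seed = 17)
  hits <- vapply(seq_len(100), function(f) {
    fr <- setCoords(tmpl@topology, frameCoords(sim$trajectory, f))
    classifyConformer(fr, lib)@label == sim$labels[f]
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("probe placement respects separation, uniformity and feasibility", {
  pts <- placeProbes(800, 50, minSep = 3, seed = 5)
  expect_equal(dim(pts), c(800, 3))
  expect_true(all(pts >= 0 & pts <= 50))
  expect_gte(min(dist(pts)), 3)
  expect_identical(pts, placeProbes(800, 50, minSep = 3, seed = 5))
  expect_error(placeProbes(10000, 10, minSep = 3, seed = 1), "infeasible")
  ## passes the coarse feasibility bound but jams during rejection sampling
  expect_error(placeProbes(80, 13, minSep = 3, seed = 1,
                           maxAttempts = 5000L), "packing failed")
})

test_that("probe counts follow the molarity closed form", {
  expect_equal(probeCountForMolarity(1e6, 1), 602L)
  expect_equal(probeCountForMolarity(33000, 1.5),
               as.integer(round(1.5 * 6.02214e23 * 33000 * 1e-27)))
  ## linear in volume up to rounding
  expect_lte(abs(probeCountForMolarity(2e6, 1) -
                 2 * probeCountForMolarity(1e6, 1)), 1)
  expect_error(probeCountForMolarity(1e6, 0), "positive")
  expect_error(probeCountForMolarity(-5, 1), "positive")
})

test_that("stand-in reference ensembles are deterministic with labelled ids", {
  e1 <- syntheticReferenceEnsemble("SMN-Tudor", seed = 2)
  e2 <- syntheticReferenceEnsemble("SMN-Tudor", seed = 2)
  expect_identical(lapply(e1$structures, coords),
                   lapply(e2$structures, coords))
  ids <- vapply(e1$structures, structureId, character(1))
  expect_true(all(grepl("^SYN-", ids)))  # synthetic, not deposited, data
  expect_length(ids, 6)
})
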