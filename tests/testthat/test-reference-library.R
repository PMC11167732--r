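## helpers to build RMSDMatrix objects directly from a numeric matrix
asRmsdMatrix <- function(m, labels = paste0("s", seq_len(nrow(m)))) {
  dimnames(m) <- list(labels, labels)
  new("RMSDMatrix", labels = labels, values = m)
}

test_that("threshold clustering finds block structure and singletons", {
  ## two tight blocks (intra < 0.5, inter > 3)
  m <- matrix(3.5, 5, 5)
  m[1:3, 1:3] <- 0.4; m[4:5, 4:5] <- 0.3
  diag(m) <- 0
  tc <- thresholdCluster(asRmsdMatrix(m), 1.2)
  expect_length(tc$clusters, 2)
  expect_setequal(tc$clusters[[1]], c("s1", "s2", "s3"))
  expect_setequal(tc$clusters[[2]], c("s4", "s5"))
  expect_length(tc$singletons, 0)
  ## all below threshold -> one cluster
  all_close <- matrix(0.5, 4, 4); diag(all_close) <- 0
  tc2 <- thresholdCluster(asRmsdMatrix(all_close), 1.2)
  expect_length(tc2$clusters, 1)
  expect_length(tc2$clusters[[1]], 4)
})

test_that("threshold clustering equals a brute-force component oracle", {
  ## 2 near closed-template, 2 near open-template, 1 isolated
  set.seed(4)
  base <- c(0, 0, 5, 5, 20)
  pts <- base + rnorm(5, sd = 0.2)
  m <- abs(outer(pts, pts, "-")) / 4  # pairwise gaps scaled to RMSD-like
  diag(m) <- 0
  tc <- thresholdCluster(asRmsdMatrix(m), 1.2)
  ## oracle: exhaustive transitive closure over the < threshold graph
  adj <- m < 1.2; diag(adj) <- FALSE
  reach <- adj | diag(5) > 0
  for (r in 1:5) reach <- reach | (reach %*% reach) > 0
  oracle_comp <- unique(apply(reach, 1, function(x) paste(which(x),
                                                          collapse = ",")))
  got <- c(vapply(tc$clusters, function(cl)
    paste(sort(match(cl, paste0("s", 1:5))), collapse = ","),
    character(1)),
    vapply(tc$singletons, function(s)
      as.character(match(s, paste0("s", 1:5))), character(1)))
  expect_setequal(got, oracle_comp)
  expect_length(tc$clusters, 2)
  expect_length(tc$singletons, 1)
})

test_that("threshold clustering is order-free and monotone in threshold", {
  ens <- sharedEnsemble("SMN-Tudor")
  m <- rmsdMatrix(ens$structures, ens$spec)
  tc <- thresholdCluster(m, 1.2)
  perm <- sample(length(ens$structures))
  m2 <- rmsdMatrix(ens$structures[perm], ens$spec)
  tc2 <- thresholdCluster(m2, 1.2)
  norm <- function(tc) lapply(c(tc$clusters, as.list(tc$singletons)), sort)
  expect_setequal(vapply(norm(tc), paste, character(1), collapse = "|"),
                  vapply(norm(tc2), paste, character(1), collapse = "|"))
  ## raising the threshold never increases the number of components
  ths <- c(0.3, 0.8, 1.2, 2.5, 6, 12)
  ncomp <- vapply(ths, function(th) {
    x <- thresholdCluster(m, th)
    length(x$clusters) + length(x$singletons)
  }, numeric(1))
  expect_true(all(diff(ncomp) <= 0))
})

test_that("library building names states, honours manual picks and errors", {
  tmpl <- leanTemplate()
  spec <- tmpl@cageSpec
  a <- stateStructure(tmpl, "closed")
  b <- stateStructure(tmpl, "open1")
  lib <- buildLibrary(list(a, b), spec)
  expect_length(lib@states, 2)
  expect_equal(vapply(lib@states, function(s) length(s@memberIds),
                      integer(1)), c(1L, 1L))
  expect_error(buildLibrary(list(a, b), spec,
                            manualPicks = c(closed = "nope")),
               "absent")
})

test_that("a noisy ensemble recovers its generating states with noise-free exemplars", {
  ens <- sharedEnsemble("SPIN1-domain1")
  lib <- buildLibrary(ens$structures, ens$spec,
                      stateNames = c("closed", "open1", "open2"))
  expect_setequal(stateNames(lib), c("closed", "open1", "open2"))
  ## the medoid of each noisy cluster is the noise-free reference
  for (s in c("closed", "open1")) {
    st <- referenceState(lib, s)
    expect_equal(st@exemplar@id, unname(ens$references[s]))
  }
  ## the singleton state is its own exemplar
  expect_equal(referenceState(lib, "open2")@exemplar@id,
               unname(ens$references["open2"]))
})

test_that("classification labels exemplars, noisy frames and novel conformers", {
  tmpl <- leanTemplate()
  spec <- tmpl@cageSpec
  refs <- lapply(stateNames(tmpl), function(s) stateStructure(tmpl, s))
  lib <- libraryFromExemplars(refs, stateNames(tmpl), spec)
  ## every exemplar classifies to itself at RMSD 0
  for (s in stateNames(tmpl)) {
    asg <- classifyConformer(referenceState(lib, s)@exemplar, lib)
    expect_equal(asg@label, s)
    expect_equal(unname(asg@rmsdToEach[s]), 0, tolerance = 1e-9)
  }
  ## a noisy open1 frame stays open1 (noise small vs inter-state RMSD)
  sim <- simulateTrajectory(tmpl, c(open1 = 1), noiseSigma = 0.2, seed = 2)
  frame <- setCoords(tmpl@topology, frameCoords(sim$trajectory, 1))
  expect_equal(classifyConformer(frame, lib)@label, "open1")
  ## a conformer far from every exemplar is novel by construction
  set.seed(99)
  far <- setCoords(refs[[1]],
                   coords(refs[[1]]) +
                     matrix(rnorm(length(coords(refs[[1]])), sd = 3),
                            ncol = 3))
  expect_equal(classifyConformer(far, lib)@label, "novel")
})

test_that("library serialization writes JSON plus exemplar PDB files", {
  tmpl <- leanTemplate()
  refs <- lapply(c("closed", "open1"), function(s) stateStructure(tmpl, s))
  lib <- libraryFromExemplars(refs, c("closed", "open1"), tmpl@cageSpec)
  dir <- file.path(tempdir(), "libtest")
  writeLibrary(lib, dir)
  meta <- jsonlite::read_json(file.path(dir, "library.json"))
  expect_equal(meta$threshold, 1.2)
  expect_equal(vapply(meta$states, function(s) s$name, character(1)),
               c("closed", "open1"))
  expect_true(file.exists(file.path(dir, "closed.pdb")))
  back <- readPDB(file.path(dir, "closed.pdb"))
  expect_equal(nrow(atomTable(back)), nrow(atomTable(refs[[1]])))
})
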