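test_that("PDB parsing is an identity on coordinates and applies record flags", {
  f <- writeTempPdb(c(
    pdbAtomLine(1, "CA", "GLY", "A", 1, 1.234, -2.5, 3.75),
    pdbAtomLine(2, "O", "HOH", "A", 90, 0, 0, 9.5, element = "O",
                record = "HETATM")))
  st <- readPDB(f)
  a <- atomTable(st)
  expect_equal(nrow(a), 2)
  expect_equal(a$x[1], 1.234)
  expect_equal(a$z[1], 3.75)
  expect_equal(a$hetatm, c(FALSE, TRUE))
  expect_equal(a$name[1], "CA")
})

test_that("alt-loc policy keeps the highest occupancy, ties break to A", {
  tie <- writeTempPdb(c(
    pdbAtomLine(1, "CB", "ALA", "A", 2, 1, 1, 1, alt = "A", occ = 0.5),
    pdbAtomLine(2, "CB", "ALA", "A", 2, 2, 2, 2, alt = "B", occ = 0.5)))
  st <- readPDB(tie)
  expect_equal(atomTable(st)$altLoc, "A")
  expect_equal(atomTable(st)$x, 1)
  win <- writeTempPdb(c(
    pdbAtomLine(1, "CB", "ALA", "A", 2, 1, 1, 1, alt = "A", occ = 0.3),
    pdbAtomLine(2, "CB", "ALA", "A", 2, 2, 2, 2, alt = "B", occ = 0.7)))
  st2 <- readPDB(win)
  expect_equal(atomTable(st2)$altLoc, "B")
  expect_equal(atomTable(st2)$x, 2)
})

test_that("single-structure mode reads model 1 of a multi-model file", {
  f <- writeTempPdb(c(
    "MODEL        1",
    pdbAtomLine(1, "CA", "GLY", "A", 1, 1, 2, 3),
    "ENDMDL",
    "MODEL        2",
    pdbAtomLine(1, "CA", "GLY", "A", 1, 9, 9, 9),
    "ENDMDL"))
  st <- readPDB(f)
  expect_equal(nrow(atomTable(st)), 1)
  expect_equal(atomTable(st)$x, 1)
})

test_that("parse errors name the offending line; empty files are rejected", {
  bad <- writeTempPdb(c(
    pdbAtomLine(1, "CA", "GLY", "A", 1, 1, 2, 3),
    "ATOM      2  CB ALA A   2       bogus   5.0     6.0"))
  expect_error(readPDB(bad), "line 2")
  empty <- writeTempPdb("REMARK nothing here")
  expect_error(readPDB(empty), "no ATOM")
  expect_error(readPDB(tempfile()), "no such file")
})

test_that("trajectory reading preserves frame order and atom counts", {
  lines <- unlist(lapply(1:3, function(m) c(
    sprintf("MODEL     %4d", m),
    pdbAtomLine(1, "CA", "GLY", "A", 1, m, 0, 0),
    "ENDMDL")))
  f <- writeTempPdb(lines)
  traj <- readTrajectory(f)
  expect_equal(nFrames(traj), 3)
  expect_equal(as.numeric(frameCoords(traj, 2)[1, 1]), 2)
})

test_that("a model with a missing atom fails naming the frame", {
  lines <- c(
    "MODEL        1",
    pdbAtomLine(1, "CA", "GLY", "A", 1, 1, 0, 0),
    pdbAtomLine(2, "CB", "GLY", "A", 1, 2, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdbAtomLine(1, "CA", "GLY", "A", 1, 1, 0, 0),
    "ENDMDL")
  expect_error(readTrajectory(writeTempPdb(lines)), "frame 2")
})

test_that("structure and trajectory writing round-trips to PDB precision", {
  tmpl <- leanTemplate()
  sim <- simulateTrajectory(tmpl, c(closed = 5, open1 = 5), seed = 3)
  f <- tempfile(fileext = ".pdb")
  writeTrajectory(sim$trajectory, f)
  back <- readTrajectory(f)
  expect_equal(nFrames(back), 10)
  ## agreement at the PDB format's 3-decimal coordinate precision
  expect_lt(max(abs(frameCoords(back, 7) -
                    frameCoords(sim$trajectory, 7))), 5.1e-4)
  ## second round trip is bit-identical
  f2 <- tempfile(fileext = ".pdb")
  writeTrajectory(back, f2)
  expect_identical(readLines(f)[2], readLines(f2)[2])
  expect_equal(frameCoords(readTrajectory(f2), 3), frameCoords(back, 3))
})

test_that("selection resolves standard side-chain heavy-atom sets", {
  ## a cage of PHE/TRP/TYR/TYR with real atom-name sets: 7+10+8+8 = 33
  ens <- sharedEnsemble("SPIN1-domain2")
  st <- ens$structures[[1]]
  sel <- resolveSelection(st, ens$spec)
  expect_length(sel@anchorIdx, 4)
  expect_length(sel@sidechainIdx, 33)
  a <- atomTable(st)
  expect_setequal(unique(a$name[sel@anchorIdx]), "CA")
  expect_false(any(a$name[sel@sidechainIdx] %in%
                     c("N", "CA", "C", "O")))
})

test_that("selection is order-independent and errors list missing atoms", {
  ens <- sharedEnsemble("SMN-Tudor")
  st <- ens$structures[[1]]
  spec <- ens$spec
  sel1 <- resolveSelection(st, spec)
  perm <- cageSpec(residues = spec@residues[c(3, 1, 4, 2), ],
                   keyPair = spec@keyPair)
  sel2 <- resolveSelection(st, perm)
  expect_setequal(sel1@anchorIdx, sel2@anchorIdx)
  expect_setequal(sel1@sidechainIdx, sel2@sidechainIdx)
  expect_equal(sort(sel1@keyPairIdx), sort(sel2@keyPairIdx))
  bad <- cageSpec(residues = spec@residues,
                  keyPair = list(c("A", 102, "XX9"), c("A", 130, "CG")))
  expect_error(resolveSelection(st, bad), "XX9")
  gone <- cageSpec(residues = rbind(spec@residues,
                                    data.frame(chain = "A", resNum = 999L,
                                               resName = "TRP")),
                   keyPair = spec@keyPair)
  expect_error(resolveSelection(st, gone), "999")
})

test_that("cage specs load from YAML config blocks with defaults", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "residues:",
    "  - [A, 62, TRP]",
    "  - [A, 72, TRP]",
    "  - [A, 251, PHE]",
    "key_pair:",
    "  - [A, 72, CH2]",
    "  - [A, 251, CG]"), f)
  spec <- readCageSpec(f)
  expect_equal(nrow(spec@residues), 3)
  expect_equal(spec@threshold, 1.2)
  expect_equal(spec@anchorAtoms, "CA")
  expect_equal(spec@keyPair$atomName, c("CH2", "CG"))
})
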