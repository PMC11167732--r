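## Synthetic aromatic-cage generator: toy cage templates with named
## conformational states (closed / open variants / collapsed), multi-state
## trajectories with ground-truth labels, probe point sets, and an
## analytic-cavity fixture. The cage is embedded in an enclosing scaffold
## shell (a minimal stand-in for the protein body around a buried pocket)
## so that pocket envelopes are bounded; side chains line the interior and
## move between states while the backbone stays fixed.

## Run code under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

unitize <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

rotationAboutAxis <- function(axis, angle) {
  u <- unitize(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## n quasi-uniform unit vectors (Fibonacci sphere).
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

## Idealized side-chain heavy-atom layouts: depth along the stem direction
## (in 1.45 A bond steps) and lateral/normal offsets (A). Tip atoms sit at
## the largest depth, mirroring the CH2/CZ/OH ring tips of Trp/Phe/Tyr.
sideChainLayout <- function(resName) {
  switch(resName,
    TRP = data.frame(
      name = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2",
               "CZ3", "CH2"),
      depth = c(1, 2, 3, 3, 4, 4, 3.4, 5, 4.6, 5.6),
      lat = c(0, 0, 0.9, -0.9, 1.1, -0.3, -1.9, 0.6, -1.9, -0.9),
      nor = c(0, 0, 0, 0, 0.2, 0, -0.2, 0.2, -0.2, 0),
      stringsAsFactors = FALSE),
    TYR = data.frame(
      name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
      depth = c(1, 2, 3, 3, 4, 4, 5, 6),
      lat = c(0, 0, 1.1, -1.1, 1.1, -1.1, 0, 0),
      nor = c(0, 0, 0.15, -0.15, 0.15, -0.15, 0, 0),
      stringsAsFactors = FALSE),
    PHE = data.frame(
      name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
      depth = c(1, 2, 3, 3, 4, 4, 5),
      lat = c(0, 0, 1.1, -1.1, 1.1, -1.1, 0),
      nor = c(0, 0, 0.15, -0.15, 0.15, -0.15, 0),
      stringsAsFactors = FALSE),
    stop("no side-chain layout for residue type '", resName, "'"))
}

elementFromName <- function(name) {
  first <- substr(name, 1, 1)
  ifelse(first %in% c("N", "O", "S"), first, "C")
}

tipAtomName <- function(resName) {
  lay <- sideChainLayout(resName)
  lay$name[which.max(lay$depth)]
}

## Default state poses: tilt is the angle (degrees) of the side-chain stem
## away from the pocket-inward direction; twist rotates the tilt plane
## about the residue axis; spread staggers the twist across residues so
## that tips interleave instead of colliding.
defaultStatePoses <- function() list(
  closed = list(tilt = 13, twist = 15, spread = 75),
  open1 = list(tilt = 58, twist = 90, spread = 10),
  open2 = list(tilt = 58, twist = -90, spread = -10),
  collapsed = list(tilt = 30, twist = 160, spread = 40)
)

BOND_STEP <- 1.45

## Build topology atoms + per-state side-chain coordinates for one cage.
buildCageGeometry <- function(residues, directions, rCage, statePoses,
                              dirJitter) {
  n_res <- nrow(residues)
  atoms <- list(); idx <- 0L
  state_side <- lapply(statePoses, function(p) list())
  for (i in seq_len(n_res)) {
    u <- unitize(directions[i, ] + dirJitter[i, ])  # outward residue axis
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    v <- unitize(cross3(u, ref)); w <- cross3(u, v)
    ca <- rCage * u
    bb <- rbind(CA = ca, N = ca + 1.46 * v, C = ca - 1.52 * v,
                O = ca - 1.52 * v + 1.23 * u)
    lay <- sideChainLayout(residues$resName[i])
    for (nm in rownames(bb)) {
      idx <- idx + 1L
      atoms[[idx]] <- data.frame(serial = idx, name = nm,
        element = elementFromName(nm), resName = residues$resName[i],
        resNum = residues$resNum[i], chain = residues$chain[i],
        x = bb[nm, 1], y = bb[nm, 2], z = bb[nm, 3], altLoc = "",
        hetatm = FALSE, stringsAsFactors = FALSE)
    }
    sc_start <- idx + 1L
    for (j in seq_len(nrow(lay))) {
      idx <- idx + 1L
      atoms[[idx]] <- data.frame(serial = idx, name = lay$name[j],
        element = elementFromName(lay$name[j]),
        resName = residues$resName[i], resNum = residues$resNum[i],
        chain = residues$chain[i], x = 0, y = 0, z = 0, altLoc = "",
        hetatm = FALSE, stringsAsFactors = FALSE)
    }
    for (s in names(statePoses)) {
      p <- statePoses[[s]]
      beta <- (p$tilt) * pi / 180
      gamma <- (p$twist + (i - 1) * p$spread) * pi / 180
      ## stem: inward (-u) tilted by beta, tilt plane twisted by gamma
      d0 <- -u * cos(beta) + w * sin(beta)
      d <- as.numeric(rotationAboutAxis(u, gamma) %*% d0)
      l <- unitize(cross3(d, u)); m <- cross3(d, l)
      pos <- t(vapply(seq_len(nrow(lay)), function(j)
        ca + BOND_STEP * lay$depth[j] * d + lay$lat[j] * l + lay$nor[j] * m,
        numeric(3)))
      state_side[[s]][[i]] <- list(first = sc_start, coords = pos)
    }
  }
  atoms <- do.call(rbind, atoms)
  list(atoms = atoms, state_side = state_side)
}

## Enclosing scaffold: two concentric atom shells around the cage so that
## the pocket interior is the only unoccupied space within pad reach of
## the side chains.
buildScaffold <- function(rInner = 8.0, rOuter = 12.0, spacingInner = 1.5,
                          spacingOuter = 2.2, resNumStart = 9001L,
                          chain = "A", serialStart = 1L) {
  mk <- function(r, s, tag, res0, serial0) {
    n <- max(12L, round(4 * pi * r^2 / s^2))
    pts <- fibonacciSphere(n) * r
    data.frame(serial = serial0 + seq_len(n) - 1L,
               name = sprintf("%s%03d", tag, seq_len(n) %% 1000),
               element = "C", resName = "SCF",
               resNum = res0 + seq_len(n) - 1L, chain = chain,
               x = pts[, 1], y = pts[, 2], z = pts[, 3], altLoc = "",
               hetatm = FALSE, stringsAsFactors = FALSE)
  }
  inner <- mk(rInner, spacingInner, "S", resNumStart, serialStart)
  outer <- mk(rOuter, spacingOuter, "T", resNumStart + nrow(inner),
              serialStart + nrow(inner))
  rbind(inner, outer)
}

#' Generate a synthetic cage template
#'
#' Builds a toy aromatic cage of \code{nRes} pseudo-residues (idealized
#' Trp/Tyr/Phe side-chain layouts on a fixed backbone) embedded in an
#' enclosing scaffold shell, with named conformational states whose
#' side-chain poses differ while all backbone/anchor atoms stay fixed. Key
#' atom pair distances per state are calibrated to \code{keyDistanceTargets}
#' by placing the tip atom at the exact designed distance. The designed
#' pairwise state RMSDs and key distances are computed (not assumed) at
#' construction, and construction fails after bounded retries if the
#' template invariants (pairwise side-chain RMSD >= 2 A between states; key
#' distance of closed differing by >= 2.5 A from every open state; closed
#' pocket volume < 10 percent of each open state's) cannot be met.
#'
#' @param nRes number of cage residues (>= 3, default 5).
#' @param seed integer; construction is deterministic per seed.
#' @param residues optional data.frame (chain, resNum, resName in TRP/TYR/
#'   PHE) overriding the default residue roster.
#' @param statePoses named list of poses (tilt, twist, spread in degrees);
#'   default closed/open1/open2/collapsed.
#' @param keyDistanceTargets named numeric of designed key distances (A)
#'   per state; NA skips calibration for a state.
#' @param keyResidueIdx integer length-2; which cage residues carry the key
#'   pair (default: residue 1 and the roughly opposite residue).
#' @param keyPairAtoms optional character length-2: atom names of the key
#'   pair on the two key residues (default: the first residue's tip atom
#'   and the second residue's CG).
#' @param minKeyGap minimum designed key-distance contrast (A) between the
#'   closed state and every open state (default 2.5; ensembles emulating
#'   published systems with smaller printed contrasts may lower it).
#' @param cavityRadius radius (A) of the analytic cavity nominally present
#'   in open states.
#' @param scaffold logical; include the enclosing shell (required for any
#'   volume work).
#' @param verifyVolume logical; verify the closed/open volume contract at
#'   construction (needs scaffold).
#' @return A \code{CageTemplate}.
#' @export
makeTemplate <- function(nRes = 5, seed = 1, residues = NULL,
                         statePoses = defaultStatePoses(),
                         keyDistanceTargets = c(closed = 6.0, open1 = 9.5,
                                                open2 = 8.9,
                                                collapsed = 4.0),
                         keyResidueIdx = NULL, keyPairAtoms = NULL,
                         minKeyGap = 2.5, cavityRadius = 3.0,
                         scaffold = TRUE, verifyVolume = scaffold) {
  if (nRes < 3) stop("nRes must be >= 3")
  if (is.null(residues)) {
    types <- rep(c("TRP", "TYR", "PHE"), length.out = nRes)
    ## residue 1 tryptophan so the deep CH2 tip anchors the key pair
    residues <- data.frame(chain = "A", resNum = 10L * seq_len(nRes),
                           resName = types, stringsAsFactors = FALSE)
  }
  n_res <- nrow(residues)
  if (is.null(keyResidueIdx)) keyResidueIdx <- c(1L, 1L + n_res %/% 2L)
  if (is.null(keyPairAtoms))
    keyPairAtoms <- c(tipAtomName(residues$resName[keyResidueIdx[1]]), "CG")
  k1 <- keyResidueIdx[1]; k2 <- keyResidueIdx[2]
  spec <- cageSpec(
    residues = residues,
    keyPair = list(c(residues$chain[k1], residues$resNum[k1],
                     keyPairAtoms[1]),
                   c(residues$chain[k2], residues$resNum[k2],
                     keyPairAtoms[2])))
  rCage <- 8.0
  for (attempt in 0:4) {
    tmpl <- withSeed(seed * 131L + attempt, {
      dirJitter <- matrix(stats::rnorm(3 * n_res, sd = 0.06), n_res, 3)
      geo <- buildCageGeometry(residues, fibonacciSphere(n_res), rCage,
                               statePoses, dirJitter)
      atoms <- geo$atoms
      if (scaffold) {
        scf <- buildScaffold(serialStart = nrow(atoms) + 1L,
                             chain = residues$chain[1])
        atoms <- rbind(atoms, scf)
      }
      base <- as.matrix(atoms[, c("x", "y", "z")])
      states <- lapply(names(statePoses), function(s) {
        xyz <- base
        for (i in seq_len(n_res)) {
          blk <- geo$state_side[[s]][[i]]
          rows <- blk$first:(blk$first + nrow(blk$coords) - 1L)
          xyz[rows, ] <- blk$coords
        }
        xyz
      })
      names(states) <- names(statePoses)
      topo <- new("CageStructure",
                  id = sprintf("syncage-seed%d", seed), atoms = atoms)
      topo <- setCoords(topo, states[[1]])
      validObject(topo)
      list(topo = topo, states = states)
    })
    topo <- tmpl$topo; states <- tmpl$states
    sel <- resolveSelection(topo, spec)
    ## calibrate key distances: move the tip atom onto the designed
    ## distance along the tip-partner line
    for (s in names(states)) {
      tgt <- keyDistanceTargets[s]
      if (is.na(tgt) || is.null(tgt) || !s %in% names(keyDistanceTargets))
        next
      xyz <- states[[s]]
      tip <- xyz[sel@keyPairIdx[1], ]; partner <- xyz[sel@keyPairIdx[2], ]
      xyz[sel@keyPairIdx[1], ] <- partner + tgt * unitize(tip - partner)
      states[[s]] <- xyz
    }
    ## measure the designed contrasts with the package's own metric
    snames <- names(states)
    structs <- lapply(snames, function(s) {
      st <- setCoords(topo, states[[s]]); st@id <- s; st
    })
    names(structs) <- snames
    gaps <- matrix(0, length(snames), length(snames),
                   dimnames = list(snames, snames))
    for (i in seq_along(snames)) for (j in seq_along(snames))
      if (i < j)
        gaps[i, j] <- gaps[j, i] <-
          sidechainRMSD(structs[[i]], structs[[j]], spec)
    keyd <- vapply(structs, function(st)
      atomPairDistance(st, sel@keyPairIdx), numeric(1))
    open_states <- grep("^open", snames, value = TRUE)
    ok <- all(gaps[upper.tri(gaps)] >= 2.0)
    if ("closed" %in% snames && length(open_states))
      ok <- ok && all(abs(keyd[open_states] - keyd["closed"]) >= minKeyGap)
    vols <- NULL
    if (ok && verifyVolume && scaffold && length(open_states) &&
        "closed" %in% snames) {
      env <- buildEnvelope(structs[open_states], spec)
      vols <- vapply(snames, function(s)
        frameVolume(structs[[s]], env), numeric(1))
      ok <- all(vols["closed"] < 0.1 * vols[open_states])
    }
    if (ok) {
      obj <- new("CageTemplate", topology = topo, states = states,
                 designedGaps = gaps, keyDistances = keyd,
                 cavitySpec = list(center = c(0, 0, 0),
                                   radius = cavityRadius,
                                   openVolumes = vols),
                 cageSpec = spec, seed = as.integer(seed))
      validObject(obj)
      return(obj)
    }
  }
  stop("template generation failed its invariants after bounded retries ",
       "(state gaps or pocket-volume contrast not achievable with the ",
       "given poses)")
}

#' Simulate a multi-state trajectory from a template
#'
#' Each frame is its segment's state coordinates plus i.i.d. Gaussian
#' coordinate noise, optionally followed by a random rigid rotation and
#' translation of the whole frame (which downstream anchor superposition
#' must remove). Segment transitions are instantaneous so segment
#' boundaries are unambiguous ground truth; \code{transitionFrames} inserts
#' linearly interpolated frames at each boundary instead (labelled by the
#' nearer endpoint state).
#'
#' @param template a \code{CageTemplate}.
#' @param segments the simulation schedule: a data.frame with columns
#'   \code{state}, \code{nFrames}, or a named numeric vector
#'   \code{c(closed = 700, open1 = 300)}.
#' @param noiseSigma per-coordinate Gaussian noise in Angstrom (default
#'   0.2).
#' @param rigidMotion apply a random rigid-body motion per frame (default
#'   TRUE).
#' @param seed integer; deterministic per seed.
#' @param transitionFrames frames of linear interpolation at each segment
#'   boundary (default 0 = instantaneous).
#' @return list with \code{trajectory} (a \code{CageTrajectory}) and
#'   \code{labels} (character ground-truth state per frame).
#' @export
simulateTrajectory <- function(template, segments, noiseSigma = 0.2,
                               rigidMotion = TRUE, seed = 1,
                               transitionFrames = 0L) {
  stopifnot(is(template, "CageTemplate"))
  if (!is.data.frame(segments))
    segments <- data.frame(state = names(segments),
                           nFrames = as.integer(segments),
                           stringsAsFactors = FALSE)
  if (any(segments$nFrames < 1)) stop("every segment needs nFrames >= 1")
  unknown <- setdiff(segments$state, names(template@states))
  if (length(unknown))
    stop("unknown state name(s): ", paste(unknown, collapse = ", "))
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  n_atoms <- nrow(template@topology@atoms)
  plan <- list(); labels <- character(0)
  for (si in seq_len(nrow(segments))) {
    if (transitionFrames > 0 && si > 1) {
      a <- segments$state[si - 1]; b <- segments$state[si]
      for (t in seq_len(transitionFrames)) {
        w <- t / (transitionFrames + 1)
        plan[[length(plan) + 1]] <-
          (1 - w) * template@states[[a]] + w * template@states[[b]]
        labels <- c(labels, if (w <= 0.5) a else b)
      }
    }
    for (f in seq_len(segments$nFrames[si])) {
      plan[[length(plan) + 1]] <- template@states[[segments$state[si]]]
      labels <- c(labels, segments$state[si])
    }
  }
  n_frames <- length(plan)
  arr <- array(0, dim = c(n_atoms, 3, n_frames))
  withSeed(seed, {
    for (f in seq_len(n_frames)) {
      xyz <- plan[[f]]
      if (noiseSigma > 0)
        xyz <- xyz + matrix(stats::rnorm(3 * n_atoms, sd = noiseSigma),
                            n_atoms, 3)
      if (rigidMotion) {
        R <- rotationAboutAxis(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
        tr <- stats::runif(3, -5, 5)
        xyz <- sweep(tcrossprod(xyz, R), 2, -tr)
      }
      arr[, , f] <- xyz
    }
  })
  traj <- new("CageTrajectory", topology = template@topology, coords = arr)
  validObject(traj)
  list(trajectory = traj, labels = labels)
}

#' Place probe points uniformly in a box with a minimum separation
#'
#' Rejection sampling with a cell list; deterministic per seed. Used to
#' emulate the homogeneous cosolvent-probe distributions whose uniformity
#' radial distribution functions verify.
#'
#' @param n number of points.
#' @param boxLengths numeric length-3 (or scalar) box edge lengths (A).
#' @param minSep minimum pairwise separation (A).
#' @param seed integer.
#' @param maxAttempts rejection budget (default 200 per point).
#' @return n x 3 matrix of points in \code{[0, boxLengths]}.
#' @export
placeProbes <- function(n, boxLengths, minSep, seed = 1,
                        maxAttempts = 200L * n) {
  if (length(boxLengths) == 1) boxLengths <- rep(boxLengths, 3)
  if (n < 1) stop("n must be >= 1")
  if (n * minSep^3 > prod(boxLengths))
    stop("packing infeasible: n * minSep^3 exceeds the box volume")
  cell <- max(minSep, 1e-6)
  ncell <- pmax(1L, as.integer(floor(boxLengths / cell)))
  cell_edge <- boxLengths / ncell  # uniform cells of edge >= minSep
  key <- function(ix) 1 + ix[1] + ncell[1] * (ix[2] + ncell[2] * ix[3])
  withSeed(seed, {
    pts <- matrix(NA_real_, n, 3)
    bins <- vector("list", prod(ncell))
    placed <- 0L; tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > maxAttempts)
        stop("packing failed after ", maxAttempts, " attempts (placed ",
             placed, " of ", n, ")")
      p <- stats::runif(3) * boxLengths
      ix <- pmin(ncell - 1L, as.integer(floor(p / cell_edge)))
      ok <- TRUE
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        jx <- ix + c(dx, dy, dz)
        if (any(jx < 0) || any(jx >= ncell)) next
        for (q in bins[[key(jx)]]) {
          if (sum((pts[q, ] - p)^2) < minSep^2) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) next
      placed <- placed + 1L
      pts[placed, ] <- p
      bins[[key(ix)]] <- c(bins[[key(ix)]], placed)
    }
    colnames(pts) <- c("x", "y", "z")
    pts
  })
}

#' Probe count achieving a target molar concentration
#'
#' @param boxVolumeA3 box volume in cubic Angstrom.
#' @param molarity target concentration in mol/L.
#' @return Integer probe count,
#'   \code{round(molarity * N_A * V[A^3] * 1e-27)}.
#' @examples
#' probeCountForMolarity(1e6, 1)  # 602
#' @export
probeCountForMolarity <- function(boxVolumeA3, molarity) {
  if (boxVolumeA3 <= 0) stop("box volume must be positive")
  if (molarity <= 0) stop("molarity must be positive")
  as.integer(round(molarity * 6.02214e23 * boxVolumeA3 * 1e-27))
}

#' Analytic-cavity fixture: a shell structure carving a known sphere
#'
#' Builds a synthetic structure whose protein atoms form a dense inner
#' shell at radius \code{cavityRadius + vdW + probe} (so the unoccupied
#' interior is a sphere of the designed radius) plus an outer sealing
#' shell, with the inner-shell atoms grouped into cage pseudo-residues.
#' Used to validate envelope volumes against the closed-form sphere volume.
#'
#' @param cavityRadius designed cavity radius in Angstrom (default 3).
#' @param radii the \code{RadiiTable} the cavity is designed for.
#' @param nResidues number of pseudo-residues the shell is split into.
#' @param seed orientation seed.
#' @return list with \code{structure} (a \code{CageStructure}),
#'   \code{spec} (a \code{CageSpec}) and \code{analyticVolume} (A^3).
#' @export
makeCavityFixture <- function(cavityRadius = 3.0, radii = defaultRadii(),
                              nResidues = 5L, seed = 1) {
  occ <- radii@radii[["C"]] + radii@probeRadius
  rInner <- cavityRadius + occ
  nInner <- max(200L, round(4 * pi * rInner^2 / 0.85^2))
  rOuter <- rInner + 3.5
  nOuter <- max(100L, round(4 * pi * rOuter^2 / 2.1^2))
  Rrot <- withSeed(seed,
                   rotationAboutAxis(stats::rnorm(3),
                                     stats::runif(1, 0, 2 * pi)))
  inner <- fibonacciSphere(nInner) %*% t(Rrot) * rInner
  outer <- fibonacciSphere(nOuter) %*% t(Rrot) * rOuter
  ## contiguous patches by azimuth -> pseudo-residues
  az <- atan2(inner[, 2], inner[, 1])
  patch <- as.integer(cut(az, breaks = seq(-pi, pi,
                                           length.out = nResidues + 1),
                          include.lowest = TRUE))
  rows <- list(); idx <- 0L
  for (res in seq_len(nResidues)) {
    members <- which(patch == res)
    ## anchor CA on the outer shell at the patch centroid direction
    cdir <- unitize(colSums(inner[members, , drop = FALSE]))
    idx <- idx + 1L
    rows[[idx]] <- data.frame(serial = idx, name = "CA", element = "C",
      resName = "CAV", resNum = res, chain = "A",
      x = rOuter * cdir[1], y = rOuter * cdir[2], z = rOuter * cdir[3],
      altLoc = "", hetatm = FALSE, stringsAsFactors = FALSE)
    for (j in seq_along(members)) {
      idx <- idx + 1L
      rows[[idx]] <- data.frame(serial = idx,
        name = sprintf("X%03d", j %% 1000), element = "C",
        resName = "CAV", resNum = res, chain = "A",
        x = inner[members[j], 1], y = inner[members[j], 2],
        z = inner[members[j], 3], altLoc = "", hetatm = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  for (j in seq_len(nOuter)) {
    idx <- idx + 1L
    rows[[idx]] <- data.frame(serial = idx,
      name = sprintf("Y%03d", j %% 1000), element = "C", resName = "SCF",
      resNum = 9000L + j, chain = "A",
      x = outer[j, 1], y = outer[j, 2], z = outer[j, 3], altLoc = "",
      hetatm = FALSE, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  st <- new("CageStructure", id = sprintf("syncavity-r%g", cavityRadius),
            atoms = atoms)
  validObject(st)
  ## key pair: two roughly opposite inner-shell atoms
  kp_res <- c(1L, 1L + nResidues %/% 2L)
  kp <- lapply(kp_res, function(r) {
    sub <- atoms[atoms$resNum == r & atoms$name != "CA", ]
    c("A", r, sub$name[1])
  })
  spec <- cageSpec(
    residues = data.frame(chain = "A", resNum = seq_len(nResidues),
                          resName = "CAV", stringsAsFactors = FALSE),
    keyPair = kp)
  list(structure = st, spec = spec,
       analyticVolume = 4 / 3 * pi * cavityRadius^3)
}
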