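## Shared fixtures (built once per test run) and independent oracles used
## to cross-check the package's numerics.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## full template with scaffold (volume-capable); built once
sharedTemplate <- function() fixture("tmpl7", function() makeTemplate(seed = 7))

## scaffold-free template for cheap geometry/trajectory tests
leanTemplate <- function()
  fixture("lean7", function() makeTemplate(seed = 7, scaffold = FALSE,
                                           verifyVolume = FALSE))

sharedEnsemble <- function(system)
  fixture(paste0("ens-", system),
          function() syntheticReferenceEnsemble(system, seed = 1))

sharedEnvelope <- function() fixture("env7", function() {
  tmpl <- sharedTemplate()
  open_refs <- lapply(grep("^open", stateNames(tmpl), value = TRUE),
                      function(s) stateStructure(tmpl, s))
  buildEnvelope(open_refs, tmpl@cageSpec)
})

## ---- tiny PDB text -------------------------------------------------------

pdbAtomLine <- function(serial, name, res, chain, resNum, x, y, z,
                        alt = "", occ = 1, element = "C",
                        record = "ATOM  ") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, res, chain, resNum, x, y, z, occ, 0,
          element)
}

writeTempPdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

## ---- brute-force rotation-grid superposition oracle ----------------------

## Exhaustive Euler-angle grid with local refinement; independent of the
## SVD route. Returns the minimum RMSD over proper rotations.
bruteForceFitRMSD <- function(mobile, ref) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(ref, 2, colMeans(ref))
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                             0, 0, 1), 3, 3)
  Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                             sin(a), 0, cos(a)), 3, 3)
  rmsdAt <- function(ang) {
    R <- Rz(ang[1]) %*% Ry(ang[2]) %*% Rz(ang[3])
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  step <- pi / 12
  best <- c(0, 0, 0); bestv <- rmsdAt(best)
  for (a in seq(0, 2 * pi - step, by = step))
    for (b in seq(0, pi, by = step))
      for (cc in seq(0, 2 * pi - step, by = step)) {
        v <- rmsdAt(c(a, b, cc))
        if (v < bestv) { bestv <- v; best <- c(a, b, cc) }
      }
  for (lev in 1:4) {
    step <- step / 4
    offsets <- seq(-3, 3) * step
    center <- best
    for (da in offsets) for (db in offsets) for (dc in offsets) {
      v <- rmsdAt(center + c(da, db, dc))
      if (v < bestv) { bestv <- v; best <- center + c(da, db, dc) }
    }
  }
  bestv
}

## ---- validity-index formula oracle ---------------------------------------

## Direct, loop-based recomputation from the medoid-form definitions.
oracleValidityIndices <- function(d, labels) {
  n <- nrow(d)
  cl <- sort(unique(labels))
  k <- length(cl)
  gm <- which.min(vapply(1:n, function(j) sum(d[, j]), numeric(1)))
  sst <- sum(d[, gm]^2)
  meds <- integer(k); sse <- 0; spread <- numeric(k)
  for (gi in seq_len(k)) {
    ix <- which(labels == cl[gi])
    meds[gi] <- ix[which.min(vapply(ix, function(j) sum(d[ix, j]),
                                    numeric(1)))]
    sse <- sse + sum(d[ix, meds[gi]]^2)
    spread[gi] <- mean(d[ix, meds[gi]])
  }
  ssr <- max(sst - sse, 0)
  psf <- (ssr / (k - 1)) / (sse / (n - k))
  dbi <- mean(vapply(seq_len(k), function(i)
    max(vapply(setdiff(seq_len(k), i), function(j)
      (spread[i] + spread[j]) / d[meds[i], meds[j]], numeric(1))),
    numeric(1)))
  c(dbi = dbi, psf = psf, ssrSst = ssr / sst)
}

## ---- step-replay average-linkage oracle -----------------------------------

## Naive agglomeration: repeatedly merge the cluster pair with the smallest
## mean cross-pair distance (computed from the original matrix). Returns
## the membership vector at every k.
oracleAverageLinkagePartitions <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    bi <- bj <- 0; bv <- Inf
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      v <- mean(d[clusters[[i]], clusters[[j]]])
      if (v < bv) { bv <- v; bi <- i; bj <- j }
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    lab <- integer(n)
    for (g in seq_along(clusters)) lab[clusters[[g]]] <- g
    partitions[[length(clusters)]] <- lab
  }
  partitions
}

## label-free canonical form of a partition (ids by first appearance)
canonicalPartition <- function(labels) {
  map <- integer(0)
  out <- integer(length(labels))
  for (i in seq_along(labels)) {
    key <- as.character(labels[i])
    if (is.na(match(key, names(map)))) {
      map[key] <- length(map) + 1L
    }
    out[i] <- map[[key]]
  }
  out
}

## coordinates of the included grid points of an envelope
envelopePoints <- function(envelope) {
  lin <- envelope@includedIdx - 1L
  d <- envelope@dims
  n12 <- d[1] * d[2]
  k <- lin %/% n12
  j <- (lin %% n12) %/% d[1]
  i <- lin %% d[1]
  cbind(envelope@origin[1] + envelope@spacing * i,
        envelope@origin[2] + envelope@spacing * j,
        envelope@origin[3] + envelope@spacing * k)
}

## random Euclidean distance matrix (points in dim-d), tie-free w.h.p.
randomDistanceMatrix <- function(n, dim = 3, seed = 1, spread = 1) {
  set.seed(seed)
  pts <- matrix(rnorm(n * dim, sd = spread), n, dim)
  as.matrix(dist(pts))
}
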