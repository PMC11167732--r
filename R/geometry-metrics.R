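## Numerical core: Kabsch superposition, side-chain RMSD under anchor-only
## prealignment, RMSD matrices, key-atom distances, RMSF and radial
## distribution functions. The single superposition convention used
## throughout the package: fit on anchor atoms only, measure on side-chain
## heavy atoms, never re-fit on the measured set.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between a
#' mobile and a reference point set, via SVD of the cross-covariance matrix
#' with the usual reflection correction.
#'
#' @param mobile n x 3 matrix of mobile coordinates.
#' @param ref n x 3 matrix of reference coordinates (same n).
#' @return A list with \code{transform} (a \code{RigidTransform} mapping
#'   mobile onto ref) and \code{rmsd} (the fit RMSD in Angstrom).
#' @export
kabschFit <- function(mobile, ref) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  if (nrow(mobile) != nrow(ref))
    stop("point-count mismatch: ", nrow(mobile), " vs ", nrow(ref))
  if (nrow(mobile) < 3) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate point configuration (collinear or coincident points)")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cr - R %*% cm)
  fitted <- tcrossprod(A, R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(transform = new("RigidTransform", rotation = R, translation = tr),
       rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param transform a \code{RigidTransform}.
#' @return Transformed n x 3 matrix.
#' @export
applyTransform <- function(xyz, transform) {
  stopifnot(is(transform, "RigidTransform"))
  sweep(tcrossprod(as.matrix(xyz), transform@rotation), 2,
        -transform@translation)
}

## Superpose full coordinates of b onto a using the anchor subsets only.
anchorSuperpose <- function(xyz_b, anchors_b, anchors_a) {
  fit <- kabschFit(anchors_b, anchors_a)
  applyTransform(xyz_b, fit$transform)
}

rmsdOf <- function(xa, xb) sqrt(mean(rowSums((xa - xb)^2)))

#' Side-chain heavy-atom RMSD between two conformers
#'
#' Superposes \code{b} onto \code{a} using the cage anchor atoms (C-alpha by
#' default), then measures the RMSD over the side-chain heavy atoms without
#' re-fitting. Atom correspondence is by (residue, atom name) through the
#' canonical ordering of \code{\link{resolveSelection}}.
#'
#' @param a,b \code{CageStructure} objects resolving \code{spec}.
#' @param spec a \code{CageSpec}.
#' @return RMSD in Angstrom.
#' @export
sidechainRMSD <- function(a, b, spec) {
  ia <- resolveSelection(a, spec)
  ib <- resolveSelection(b, spec)
  if (length(ia@sidechainIdx) != length(ib@sidechainIdx)) {
    na <- a@atoms$name[ia@sidechainIdx]
    nb <- b@atoms$name[ib@sidechainIdx]
    stop("side-chain atom sets differ between '", a@id, "' and '", b@id,
         "': unmatched ", paste(union(setdiff(na, nb), setdiff(nb, na)),
                                collapse = ", "))
  }
  xa <- coords(a); xb <- coords(b)
  xb_fit <- anchorSuperpose(xb, xb[ib@anchorIdx, , drop = FALSE],
                            xa[ia@anchorIdx, , drop = FALSE])
  rmsdOf(xa[ia@sidechainIdx, , drop = FALSE],
         xb_fit[ib@sidechainIdx, , drop = FALSE])
}

#' Pairwise side-chain RMSD matrix over an ensemble of structures
#'
#' @param structures list of \code{CageStructure} objects (>= 2), all
#'   resolving \code{spec}.
#' @param spec a \code{CageSpec}.
#' @return An \code{RMSDMatrix} labelled by structure ids.
#' @export
rmsdMatrix <- function(structures, spec) {
  if (length(structures) < 2) stop("need at least 2 structures")
  n <- length(structures)
  labels <- vapply(structures, structureId, character(1))
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      v <- tryCatch(sidechainRMSD(structures[[i]], structures[[j]], spec),
                    error = function(e)
                      stop("RMSD between '", labels[i], "' and '", labels[j],
                           "' failed: ", conditionMessage(e)))
      m[i, j] <- m[j, i] <- v
    }
  }
  new("RMSDMatrix", labels = labels, values = m)
}

#' Write an RMSD matrix as TSV
#'
#' @param m an \code{RMSDMatrix}.
#' @param path output path; header row carries the structure ids.
#' @return \code{path}, invisibly.
#' @export
writeRMSDMatrix <- function(m, path) {
  stopifnot(is(m, "RMSDMatrix"))
  df <- data.frame(id = m@labels, m@values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Euclidean distance between a key atom pair
#'
#' @param x a \code{CageStructure} or an n x 3 coordinate matrix.
#' @param keyPairIdx integer length-2 atom indices, e.g. from
#'   \code{\link{resolveSelection}}.
#' @return Distance in Angstrom.
#' @examples
#' atomPairDistance(rbind(c(0, 0, 0), c(3, 4, 0)), c(1, 2))  # 5
#' @export
atomPairDistance <- function(x, keyPairIdx) {
  xyz <- if (is(x, "CageStructure")) coords(x) else as.matrix(x)
  if (any(keyPairIdx < 1 | keyPairIdx > nrow(xyz)))
    stop("key pair index out of range (n_atoms = ", nrow(xyz), ")")
  sqrt(sum((xyz[keyPairIdx[1], ] - xyz[keyPairIdx[2], ])^2))
}

#' Superpose every trajectory frame onto a reference frame
#'
#' Fits each frame's anchor atoms onto the anchor atoms of the reference
#' frame (frame 1 by default) and applies the transform to all atoms: the
#' one-time prealignment used before frame-to-frame side-chain RMSD.
#'
#' @param trajectory a \code{CageTrajectory}.
#' @param anchorIdx integer anchor atom indices.
#' @param refFrame reference frame number.
#' @return A \code{CageTrajectory} with superposed coordinates.
#' @export
alignTrajectory <- function(trajectory, anchorIdx, refFrame = 1) {
  stopifnot(is(trajectory, "CageTrajectory"))
  ref <- frameCoords(trajectory, refFrame)[anchorIdx, , drop = FALSE]
  out <- trajectory@coords
  for (f in seq_len(nFrames(trajectory))) {
    fr <- frameCoords(trajectory, f)
    out[, , f] <- anchorSuperpose(fr, fr[anchorIdx, , drop = FALSE], ref)
  }
  trajectory@coords <- out
  trajectory
}

#' Per-atom root-mean-square fluctuation
#'
#' RMSF of atom i is the square root of the mean squared deviation from the
#' atom's mean position over frames. Unless \code{prealigned}, frames are
#' first superposed onto frame 1 via \code{anchorIdx}.
#'
#' @param trajectory a \code{CageTrajectory}.
#' @param selection integer atom indices to report (default: all atoms).
#' @param anchorIdx anchor indices used for internal superposition.
#' @param prealigned set TRUE if the trajectory is already superposed.
#' @return Named numeric vector of RMSF values (Angstrom) for
#'   \code{selection}.
#' @export
rmsf <- function(trajectory, selection = NULL, anchorIdx = NULL,
                 prealigned = FALSE) {
  stopifnot(is(trajectory, "CageTrajectory"))
  n <- nFrames(trajectory)
  if (n == 1) {
    warning("single-frame trajectory: RMSF is identically zero")
    sel <- if (is.null(selection)) seq_len(dim(trajectory@coords)[1])
           else selection
    return(stats::setNames(numeric(length(sel)),
                           trajectory@topology@atoms$name[sel]))
  }
  if (!prealigned) {
    if (is.null(anchorIdx))
      stop("supply anchorIdx for internal superposition or set prealigned")
    trajectory <- alignTrajectory(trajectory, anchorIdx)
  }
  sel <- if (is.null(selection)) seq_len(dim(trajectory@coords)[1])
         else selection
  xs <- trajectory@coords[sel, , , drop = FALSE]
  mu <- apply(xs, c(1, 2), mean)
  dev2 <- sweep(xs, c(1, 2), mu)^2
  out <- sqrt(apply(dev2, 1, sum) / n)
  stats::setNames(out, trajectory@topology@atoms$name[sel])
}

#' Radial distribution function g(r)
#'
#' Histogram of center-probe distances normalized by the ideal-gas shell
#' expectation, so that probes uniformly distributed over the reference
#' volume give g(r) of about 1. Non-periodic: distances are plain Euclidean
#' and the number density is taken as n_probes / box volume.
#'
#' @param centers m x 3 matrix of center points.
#' @param probes n x 3 matrix of probe points.
#' @param dr bin width in Angstrom (default 0.1).
#' @param rMax maximum radius.
#' @param boxVolume reference volume used for the probe number density; by
#'   default the bounding-box volume of the probe set.
#' @return data.frame with columns \code{r} (bin centers) and \code{g}.
#' @export
radialDistribution <- function(centers, probes, dr = 0.1, rMax,
                               boxVolume = NULL) {
  centers <- as.matrix(centers); probes <- as.matrix(probes)
  if (nrow(probes) == 0) stop("empty probe point set")
  if (nrow(centers) == 0) stop("empty center point set")
  if (dr <= 0) stop("dr must be positive")
  if (rMax <= dr) stop("rMax must exceed dr")
  if (is.null(boxVolume)) {
    span <- apply(probes, 2, range)
    boxVolume <- prod(span[2, ] - span[1, ])
  }
  rho <- nrow(probes) / boxVolume
  breaks <- seq(0, rMax, by = dr)
  if (breaks[length(breaks)] < rMax) breaks <- c(breaks, rMax)
  counts <- numeric(length(breaks) - 1)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(colSums((t(probes) - centers[i, ])^2))
    d <- d[d < rMax & d > 0]
    counts <- counts + tabulate(findInterval(d, breaks), length(counts))
  }
  shell <- 4 / 3 * pi * diff(breaks^3)
  g <- counts / (nrow(centers) * rho * shell)
  data.frame(r = (breaks[-length(breaks)] + breaks[-1]) / 2, g = g)
}

#' Write a g(r) curve as two-column TSV
#'
#' @param gr data.frame from \code{\link{radialDistribution}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRDF <- function(gr, path) {
  utils::write.table(gr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
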