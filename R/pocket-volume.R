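## Occupancy-grid pocket volume: a fixed envelope derived from open
## reference structures, inside which per-frame unoccupied volume is
## counted. A grid point is occupied when it lies within (vdW + probe)
## of any protein heavy atom.

#' Default van der Waals radii table
#'
#' @param probeRadius solvent probe radius in Angstrom (default 1.4).
#' @return A \code{RadiiTable} with C 1.70, N 1.55, O 1.52, S 1.80 and a
#'   1.70 default for other elements.
#' @export
defaultRadii <- function(probeRadius = 1.4) {
  new("RadiiTable",
      radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80),
      defaultRadius = 1.70, probeRadius = probeRadius)
}

elementRadii <- function(elements, radii) {
  r <- radii@radii[toupper(trimws(elements))]
  r[is.na(r)] <- radii@defaultRadius
  unname(r)
}

## Mark grid points within per-atom radius of any atom. Returns a logical
## vector over the full grid (column-major linear indexing). Each atom only
## touches its local window of cells, so cost is O(n_atoms * window).
markWithin <- function(xyz, r, origin, spacing, dims) {
  occ <- logical(prod(dims))
  if (nrow(xyz) == 0) return(occ)
  n12 <- dims[1] * dims[2]
  hi <- origin + (dims - 1) * spacing
  for (a in seq_len(nrow(xyz))) {
    p <- xyz[a, ]; ra <- r[a]
    if (any(p + ra < origin) || any(p - ra > hi)) next
    i0 <- pmax(0L, as.integer(ceiling((p - ra - origin) / spacing)))
    i1 <- pmin(dims - 1L, as.integer(floor((p + ra - origin) / spacing)))
    if (any(i1 < i0)) next
    ii <- i0[1]:i1[1]; jj <- i0[2]:i1[2]; kk <- i0[3]:i1[3]
    dx2 <- (origin[1] + spacing * ii - p[1])^2
    dy2 <- (origin[2] + spacing * jj - p[2])^2
    dz2 <- (origin[3] + spacing * kk - p[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    lin <- outer(outer(1L + ii, dims[1] * jj, "+"), n12 * kk, "+")
    occ[lin[d2 <= ra^2]] <- TRUE
  }
  occ
}

proteinHeavyMask <- function(atoms) !atoms$hetatm & !isHydrogen(atoms)

#' Build a pocket envelope from open reference structures
#'
#' All references are superposed onto the first via the cage anchor atoms.
#' The grid spans the bounding box of the cage side-chain atoms plus
#' \code{pad}; a grid point belongs to the envelope if, in at least one
#' reference, it is within \code{pad} of a cage side-chain atom and
#' unoccupied (farther than vdW + probe from every protein heavy atom).
#' The union over references is taken, and the envelope is frozen: the same
#' shape is scanned across all trajectory frames afterwards.
#'
#' @param openReferences list of \code{CageStructure} (>= 1) in open cage
#'   conformation.
#' @param spec a \code{CageSpec}.
#' @param radii a \code{RadiiTable}.
#' @param pad Angstrom (default 5.0).
#' @param spacing grid spacing in Angstrom (default 0.5).
#' @return A \code{PocketEnvelope}.
#' @export
buildEnvelope <- function(openReferences, spec, radii = defaultRadii(),
                          pad = 5.0, spacing = 0.5) {
  if (is(openReferences, "CageStructure"))
    openReferences <- list(openReferences)
  if (length(openReferences) < 1) stop("need at least 1 open reference")
  sels <- lapply(openReferences, resolveSelection, spec = spec)
  ref_anchor <- coords(openReferences[[1]])[sels[[1]]@anchorIdx, ,
                                            drop = FALSE]
  fitted <- lapply(seq_along(openReferences), function(i) {
    xyz <- coords(openReferences[[i]])
    if (i == 1) return(xyz)
    anchorSuperpose(xyz, xyz[sels[[i]]@anchorIdx, , drop = FALSE],
                    ref_anchor)
  })
  sc_all <- do.call(rbind, lapply(seq_along(fitted), function(i)
    fitted[[i]][sels[[i]]@sidechainIdx, , drop = FALSE]))
  lo <- apply(sc_all, 2, min) - pad
  hi <- apply(sc_all, 2, max) + pad
  origin <- floor(lo / spacing) * spacing
  dims <- as.integer(ceiling((hi - origin) / spacing)) + 1L
  inc <- logical(prod(dims))
  for (i in seq_along(fitted)) {
    atoms <- openReferences[[i]]@atoms
    heavy <- proteinHeavyMask(atoms)
    occ <- markWithin(fitted[[i]][heavy, , drop = FALSE],
                      elementRadii(atoms$element[heavy], radii) +
                        radii@probeRadius,
                      origin, spacing, dims)
    sc <- fitted[[i]][sels[[i]]@sidechainIdx, , drop = FALSE]
    near <- markWithin(sc, rep(pad, nrow(sc)), origin, spacing, dims)
    inc <- inc | (near & !occ)
  }
  if (!any(inc))
    stop("empty envelope: no unoccupied grid points within ", pad,
         " A of the cage side chains")
  obj <- new("PocketEnvelope", origin = origin, spacing = spacing,
             dims = dims, includedIdx = which(inc),
             refAnchorCoords = ref_anchor, cageSpec = spec,
             provenance = list(
               reference_ids = vapply(openReferences, structureId,
                                      character(1)),
               spacing = spacing, pad = pad,
               probe_radius = radii@probeRadius,
               radii = as.list(radii@radii),
               default_radius = radii@defaultRadius))
  validObject(obj)
  obj
}

## Occupied mask restricted to the envelope's grid for one coordinate set.
envelopeOccupied <- function(xyz, r, envelope) {
  markWithin(xyz, r, envelope@origin, envelope@spacing, envelope@dims)
}

#' Unoccupied pocket volume of one conformation
#'
#' Superposes the conformation onto the envelope's reference frame via the
#' cage anchors, then counts envelope grid points farther than vdW + probe
#' from every protein heavy atom.
#'
#' @param x a \code{CageStructure}, or an n x 3 coordinate matrix (a matrix
#'   with zero rows yields the full envelope volume).
#' @param envelope a \code{PocketEnvelope}.
#' @param radii a \code{RadiiTable}.
#' @param indexSets an \code{AtomIndexSets} for matrix input (anchors used
#'   for superposition); NULL means the coordinates are already in the
#'   envelope's frame.
#' @param elements element symbols for matrix input (default all carbon).
#' @return Volume in cubic Angstrom.
#' @export
frameVolume <- function(x, envelope, radii = defaultRadii(),
                        indexSets = NULL, elements = NULL) {
  stopifnot(is(envelope, "PocketEnvelope"))
  if (is(x, "CageStructure")) {
    atoms <- x@atoms
    heavy <- proteinHeavyMask(atoms)
    sel <- resolveSelection(x, envelope@cageSpec)
    xyz <- coords(x)
    xyz <- anchorSuperpose(xyz, xyz[sel@anchorIdx, , drop = FALSE],
                           envelope@refAnchorCoords)
    xyz <- xyz[heavy, , drop = FALSE]
    r <- elementRadii(atoms$element[heavy], radii) + radii@probeRadius
  } else {
    xyz <- as.matrix(x)
    if (nrow(xyz) > 0 && !is.null(indexSets))
      xyz <- anchorSuperpose(xyz, xyz[indexSets@anchorIdx, , drop = FALSE],
                             envelope@refAnchorCoords)
    if (is.null(elements)) elements <- rep("C", nrow(xyz))
    r <- elementRadii(elements, radii) + radii@probeRadius
  }
  occ <- envelopeOccupied(xyz, r, envelope)
  sum(!occ[envelope@includedIdx]) * envelope@spacing^3
}

#' Pocket volume per trajectory frame
#'
#' @param trajectory a \code{CageTrajectory}.
#' @param envelope a \code{PocketEnvelope}.
#' @param radii a \code{RadiiTable}.
#' @param stride keep every stride-th frame.
#' @param frames explicit frame numbers (overrides stride).
#' @return data.frame with columns \code{frame} and \code{volume} (A^3),
#'   in frame order.
#' @export
volumeSeries <- function(trajectory, envelope, radii = defaultRadii(),
                         stride = 1L, frames = NULL) {
  stopifnot(is(trajectory, "CageTrajectory"), is(envelope, "PocketEnvelope"))
  if (is.null(frames))
    frames <- seq(1L, nFrames(trajectory), by = as.integer(stride))
  atoms <- trajectory@topology@atoms
  heavy <- proteinHeavyMask(atoms)
  sel <- resolveSelection(trajectory@topology, envelope@cageSpec)
  r <- elementRadii(atoms$element[heavy], radii) + radii@probeRadius
  vols <- vapply(frames, function(f) {
    xyz <- frameCoords(trajectory, f)
    xyz <- anchorSuperpose(xyz, xyz[sel@anchorIdx, , drop = FALSE],
                           envelope@refAnchorCoords)
    occ <- envelopeOccupied(xyz[heavy, , drop = FALSE], r, envelope)
    sum(!occ[envelope@includedIdx]) * envelope@spacing^3
  }, numeric(1))
  data.frame(frame = as.integer(frames), volume = vols)
}

#' Persist a pocket envelope as plain text
#'
#' Writes \code{<path>} with a small header (origin, spacing, dims) and one
#' included grid triple per line, plus \code{<path>.json} with provenance.
#'
#' @param envelope a \code{PocketEnvelope}.
#' @param path output path (e.g. "envelope.grid").
#' @return \code{path}, invisibly.
#' @export
writeEnvelope <- function(envelope, path) {
  stopifnot(is(envelope, "PocketEnvelope"))
  lin <- envelope@includedIdx - 1L
  n12 <- envelope@dims[1] * envelope@dims[2]
  k <- lin %/% n12
  j <- (lin %% n12) %/% envelope@dims[1]
  i <- lin %% envelope@dims[1]
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# origin %.6f %.6f %.6f", envelope@origin[1],
            envelope@origin[2], envelope@origin[3]),
    sprintf("# spacing %.6f", envelope@spacing),
    sprintf("# dims %d %d %d", envelope@dims[1], envelope@dims[2],
            envelope@dims[3]),
    sprintf("%d %d %d", i, j, k)), con)
  jsonlite::write_json(envelope@provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
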