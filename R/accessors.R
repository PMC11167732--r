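#' Accessors for cageflex objects
#'
#' Small generic accessors so that downstream code never touches slots
#' directly.
#'
#' @param x an object.
#' @param ... unused.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("structureId", function(x, ...) standardGeneric("structureId"))

#' @rdname accessors
#' @export
setMethod("structureId", "CageStructure", function(x, ...) x@id)

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x, ...) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setMethod("atomTable", "CageStructure", function(x, ...) x@atoms)

#' @rdname accessors
#' @export
setMethod("atomTable", "CageTrajectory", function(x, ...) x@topology@atoms)

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setMethod("coords", "CageStructure", function(x, ...) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
})

#' @rdname accessors
#' @export
setMethod("coords", "CageTrajectory", function(x, ...) x@coords)

#' @rdname accessors
#' @export
setGeneric("topology", function(x, ...) standardGeneric("topology"))

#' @rdname accessors
#' @export
setMethod("topology", "CageTrajectory", function(x, ...) x@topology)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x, ...) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setMethod("nFrames", "CageTrajectory", function(x, ...) dim(x@coords)[3])

#' Extract one frame of a trajectory as a coordinate matrix
#'
#' @param trajectory a \code{CageTrajectory}.
#' @param i frame number (1-based).
#' @return n_atoms x 3 numeric matrix.
#' @export
frameCoords <- function(trajectory, i) {
  stopifnot(is(trajectory, "CageTrajectory"))
  n <- nFrames(trajectory)
  if (i < 1 || i > n) stop("frame index ", i, " out of range [1, ", n, "]")
  m <- trajectory@coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Replace the coordinates of a structure
#'
#' @param structure a \code{CageStructure}.
#' @param xyz n_atoms x 3 matrix.
#' @return A \code{CageStructure} with updated coordinates.
#' @export
setCoords <- function(structure, xyz) {
  stopifnot(is(structure, "CageStructure"))
  if (nrow(xyz) != nrow(structure@atoms))
    stop("coordinate row count does not match atom count")
  structure@atoms$x <- xyz[, 1]
  structure@atoms$y <- xyz[, 2]
  structure@atoms$z <- xyz[, 3]
  validObject(structure)
  structure
}

#' @rdname accessors
#' @export
setGeneric("stateNames", function(x, ...) standardGeneric("stateNames"))

#' @rdname accessors
#' @export
setMethod("stateNames", "ReferenceLibrary", function(x, ...)
  vapply(x@states, function(s) s@name, character(1)))

#' @rdname accessors
#' @export
setMethod("stateNames", "CageTemplate", function(x, ...) names(x@states))

#' Retrieve one reference state from a library
#'
#' @param library a \code{ReferenceLibrary}.
#' @param name state name.
#' @return A \code{ReferenceState}.
#' @export
referenceState <- function(library, name) {
  stopifnot(is(library, "ReferenceLibrary"))
  nm <- stateNames(library)
  if (!name %in% nm) stop("no state named '", name, "' in library")
  library@states[[match(name, nm)]]
}

#' Materialize one template state as a structure
#'
#' @param template a \code{CageTemplate}.
#' @param state state name.
#' @return A \code{CageStructure} with the state's coordinates.
#' @export
stateStructure <- function(template, state) {
  stopifnot(is(template, "CageTemplate"))
  if (!state %in% names(template@states))
    stop("unknown state '", state, "'; template has: ",
         paste(names(template@states), collapse = ", "))
  s <- setCoords(template@topology, template@states[[state]])
  s@id <- paste0(template@topology@id, ":", state)
  s
}

#' Total volume of a pocket envelope
#'
#' @param envelope a \code{PocketEnvelope}.
#' @return Volume in cubic Angstrom.
#' @export
envelopeVolume <- function(envelope) {
  stopifnot(is(envelope, "PocketEnvelope"))
  length(envelope@includedIdx) * envelope@spacing^3
}

setMethod("show", "CageStructure", function(object) {
  a <- object@atoms
  cat("CageStructure '", object@id, "': ", nrow(a), " atoms, ",
      length(unique(paste(a$chain, a$resNum))), " residues, ",
      sum(a$hetatm), " HETATM\n", sep = "")
})

setMethod("show", "CageTrajectory", function(object) {
  d <- dim(object@coords)
  cat("CageTrajectory: ", d[3], " frames x ", d[1], " atoms (topology '",
      object@topology@id, "')\n", sep = "")
})

setMethod("show", "CageSpec", function(object) {
  r <- object@residues
  cat("CageSpec: ", nrow(r), " residues (",
      paste(paste0(r$resName, r$resNum), collapse = ", "),
      "), threshold ", object@threshold, " A\n", sep = "")
  kp <- object@keyPair
  cat("  key pair: ", kp$resNum[1], "-", kp$atomName[1], " to ",
      kp$resNum[2], "-", kp$atomName[2], "\n", sep = "")
})

setMethod("show", "ReferenceLibrary", function(object) {
  cat("ReferenceLibrary: ", length(object@states), " states at threshold ",
      object@threshold, " A\n", sep = "")
  for (s in object@states)
    cat("  ", s@name, ": exemplar '", s@exemplar@id, "', ",
        length(s@memberIds), " members\n", sep = "")
})

setMethod("show", "ClusteringResult", function(object) {
  cat("ClusteringResult: k = ", object@k, ", fractions ",
      paste(sprintf("%.3f", object@populationFraction), collapse = "/"),
      "\n  indices: dbi ", signif(object@indices["dbi"], 4),
      ", psf ", signif(object@indices["psf"], 4),
      ", ssr/sst ", signif(object@indices["ssrSst"], 4), "\n", sep = "")
})

setMethod("show", "KSweepReport", function(object) {
  ks <- vapply(object@results, function(r) r@k, integer(1))
  cat("KSweepReport: k in [", min(ks), ", ", max(ks), "], selected k = ",
      object@selectedK, " (", object@selectionRule, ")\n", sep = "")
})

setMethod("show", "PocketEnvelope", function(object) {
  cat("PocketEnvelope: ", length(object@includedIdx), " grid points at ",
      object@spacing, " A spacing = ", round(envelopeVolume(object), 1),
      " A^3\n", sep = "")
})

setMethod("show", "CageTemplate", function(object) {
  cat("CageTemplate '", object@topology@id, "': states ",
      paste(names(object@states), collapse = ", "), "\n", sep = "")
  cat("  key distances [A]: ",
      paste(sprintf("%s %.2f", names(object@keyDistances),
                    object@keyDistances), collapse = ", "), "\n", sep = "")
})

setMethod("show", "StateAssignment", function(object) {
  cat("StateAssignment: '", object@label, "' (RMSD ",
      paste(sprintf("%s %.3f", names(object@rmsdToEach), object@rmsdToEach),
            collapse = ", "), ")\n", sep = "")
})

#' Construct a structure from an atom table
#'
#' @param id structure label.
#' @param atoms data.frame with the \code{CageStructure} atom columns
#'   (\code{serial}, \code{name}, \code{element}, \code{resName},
#'   \code{resNum}, \code{chain}, \code{x}, \code{y}, \code{z},
#'   \code{altLoc}, \code{hetatm}); missing serial/element/altLoc/hetatm
#'   columns are filled with defaults.
#' @return A \code{CageStructure}.
#' @export
cageStructure <- function(id, atoms) {
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$element))
    atoms$element <- substr(toupper(atoms$name), 1, 1)
  if (is.null(atoms$altLoc)) atoms$altLoc <- ""
  if (is.null(atoms$hetatm)) atoms$hetatm <- FALSE
  obj <- new("CageStructure", id = id,
             atoms = atoms[, c("serial", "name", "element", "resName",
                               "resNum", "chain", "x", "y", "z", "altLoc",
                               "hetatm")])
  validObject(obj)
  obj
}

#' Construct a trajectory from a topology and a coordinate array
#'
#' @param topology a \code{CageStructure}.
#' @param coords n_atoms x 3 x n_frames array, or a list of n_atoms x 3
#'   matrices.
#' @return A \code{CageTrajectory}.
#' @export
cageTrajectory <- function(topology, coords) {
  if (is.list(coords)) {
    arr <- array(0, dim = c(nrow(coords[[1]]), 3, length(coords)))
    for (f in seq_along(coords)) arr[, , f] <- coords[[f]]
    coords <- arr
  }
  obj <- new("CageTrajectory", topology = topology, coords = coords)
  validObject(obj)
  obj
}
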