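#' @import methods
NULL

## Central S4 containers. Coordinates are always Angstrom; atom tables are
## plain data.frames so that subsetting and I/O stay transparent.

#' Declarative definition of an aromatic cage
#'
#' A \code{CageSpec} names the residues forming an aromatic cage, the anchor
#' atoms used for superposition (C-alpha by default), the backbone atom names
#' excluded from the side-chain heavy-atom set, the key atom pair whose
#' distance separates open from closed states, and the RMSD threshold (in
#' Angstrom) below which a conformation counts as assigned to a state.
#'
#' @slot residues data.frame with columns \code{chain}, \code{resNum},
#'   \code{resName}; one row per cage residue.
#' @slot anchorAtoms character; atom names used as superposition anchors
#'   (default \code{"CA"}).
#' @slot sidechainExclusions character; backbone atom names excluded from the
#'   side-chain set. Hydrogens are excluded everywhere regardless.
#' @slot keyPair data.frame with two rows and columns \code{chain},
#'   \code{resNum}, \code{atomName}; the distance-tracking atom pair.
#' @slot threshold numeric; assignment threshold in Angstrom (default 1.2).
#' @exportClass CageSpec
setClass("CageSpec",
  representation(
    residues = "data.frame",
    anchorAtoms = "character",
    sidechainExclusions = "character",
    keyPair = "data.frame",
    threshold = "numeric"
  )
)

setValidity("CageSpec", function(object) {
  msgs <- character(0)
  req <- c("chain", "resNum", "resName")
  if (!all(req %in% names(object@residues)))
    msgs <- c(msgs, "residues must have columns chain, resNum, resName")
  if (nrow(object@residues) < 1)
    msgs <- c(msgs, "residues must be non-empty")
  if (!all(c("chain", "resNum", "atomName") %in% names(object@keyPair)) ||
      nrow(object@keyPair) != 2)
    msgs <- c(msgs, "keyPair must have 2 rows with chain, resNum, atomName")
  if (length(object@threshold) != 1 || !is.finite(object@threshold) ||
      object@threshold <= 0)
    msgs <- c(msgs, "threshold must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' A single conformer with typed atoms
#'
#' @slot id character label (e.g. a PDB code or a synthetic id).
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resName}, \code{resNum}, \code{chain}, \code{x},
#'   \code{y}, \code{z}, \code{altLoc}, \code{hetatm}.
#' @exportClass CageStructure
setClass("CageStructure",
  representation(id = "character", atoms = "data.frame")
)

setValidity("CageStructure", function(object) {
  a <- object@atoms
  req <- c("serial", "name", "element", "resName", "resNum", "chain",
           "x", "y", "z", "altLoc", "hetatm")
  if (!all(req %in% names(a)))
    return(paste("atoms must have columns:", paste(req, collapse = ", ")))
  if (nrow(a) == 0) return("structure must contain at least one atom")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("all coordinates must be finite")
  if (any(!nzchar(a$name))) return("atom names must be non-empty")
  key <- paste(a$chain, a$resNum, a$name, a$altLoc)
  if (anyDuplicated(key))
    return("(chain, resNum, name, altLoc) must be unique per structure")
  TRUE
})

#' An ordered frame sequence sharing one topology
#'
#' @slot topology \code{CageStructure}; atom ordering authority.
#' @slot coords numeric array of dimension \code{n_atoms x 3 x n_frames}.
#' @exportClass CageTrajectory
setClass("CageTrajectory",
  representation(topology = "CageStructure", coords = "array")
)

setValidity("CageTrajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[1] != nrow(object@topology@atoms))
    return("frame atom count must match the topology")
  if (d[3] < 1) return("a trajectory needs at least one frame")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  TRUE
})

#' Resolved atom index sets for a cage on one topology
#'
#' @slot anchorIdx integer indices of anchor atoms (one per cage residue,
#'   spec residue order).
#' @slot sidechainIdx integer indices of side-chain heavy atoms, in canonical
#'   (residue, atom-name) order so that selections on different structures
#'   correspond atom by atom.
#' @slot keyPairIdx integer length-2.
#' @exportClass AtomIndexSets
setClass("AtomIndexSets",
  representation(anchorIdx = "integer", sidechainIdx = "integer",
                 keyPairIdx = "integer")
)

setValidity("AtomIndexSets", function(object) {
  if (length(intersect(object@anchorIdx, object@sidechainIdx)))
    return("anchor and side-chain index sets must be disjoint")
  if (length(object@keyPairIdx) != 2) return("keyPairIdx must have length 2")
  TRUE
})

#' A rigid-body transform (proper rotation + translation)
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric length-3, Angstrom.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric")
)

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation must be orthonormal")
  if (abs(det(R) - 1) > 1e-6) return("rotation must have determinant +1")
  if (length(object@translation) != 3) return("translation must be length 3")
  TRUE
})

#' Symmetric matrix of pairwise side-chain RMSD values
#'
#' @slot labels character; ordered structure ids.
#' @slot values numeric symmetric matrix (Angstrom), zero diagonal.
#' @exportClass RMSDMatrix
setClass("RMSDMatrix",
  representation(labels = "character", values = "matrix")
)

setValidity("RMSDMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (nrow(v) != length(object@labels))
    return("labels must match matrix dimension")
  if (any(v < 0)) return("RMSD values must be non-negative")
  if (max(abs(v - t(v))) > 1e-9) return("values must be symmetric")
  if (max(abs(diag(v))) > 1e-9) return("diagonal must be zero")
  TRUE
})

#' One named reference conformational state
#'
#' @slot name character label (e.g. "closed", "open1").
#' @slot exemplar \code{CageStructure}; the state's representative conformer.
#' @slot memberIds character; structure ids belonging to the state's cluster.
#' @slot descriptors named numeric; \code{keyDistance} (Angstrom) and
#'   \code{pocketVolume} (cubic Angstrom) of the exemplar (NA until measured).
#' @exportClass ReferenceState
setClass("ReferenceState",
  representation(name = "character", exemplar = "CageStructure",
                 memberIds = "character", descriptors = "numeric")
)

#' Library of named reference states
#'
#' @slot states list of \code{ReferenceState}.
#' @slot threshold numeric; assignment threshold (Angstrom).
#' @slot cageSpec \code{CageSpec} shared by all states.
#' @exportClass ReferenceLibrary
setClass("ReferenceLibrary",
  representation(states = "list", threshold = "numeric",
                 cageSpec = "CageSpec")
)

setValidity("ReferenceLibrary", function(object) {
  nm <- vapply(object@states, function(s) s@name, character(1))
  if (anyDuplicated(nm)) return("state names must be unique")
  TRUE
})

#' Assignment of one conformer to a reference state
#'
#' @slot label character; a state name or "novel".
#' @slot rmsdToEach named numeric; side-chain RMSD to every state exemplar.
#' @exportClass StateAssignment
setClass("StateAssignment",
  representation(label = "character", rmsdToEach = "numeric")
)

#' Pairwise side-chain RMSD matrix over (strided) trajectory frames
#'
#' @slot frameIndices integer; original frame numbers of the rows.
#' @slot values numeric symmetric matrix (Angstrom).
#' @exportClass FrameDistanceMatrix
setClass("FrameDistanceMatrix",
  representation(frameIndices = "integer", values = "matrix")
)

#' Result of one agglomerative clustering cut
#'
#' Cluster ids are 0-based, mirroring the numbering convention of common
#' trajectory-analysis tools.
#'
#' @slot k integer cluster count.
#' @slot labels integer in \code{[0, k)}, one per (strided) frame.
#' @slot frameIndices integer; original frame numbers of the clustered
#'   (strided) frames, parallel to \code{labels}.
#' @slot medoidFrame integer; original frame number of each cluster's medoid.
#' @slot populationFraction numeric per cluster, sums to 1.
#' @slot indices named numeric: \code{dbi}, \code{psf}, \code{ssrSst}.
#' @exportClass ClusteringResult
setClass("ClusteringResult",
  representation(k = "integer", labels = "integer",
                 frameIndices = "integer", medoidFrame = "integer",
                 populationFraction = "numeric", indices = "numeric")
)

setValidity("ClusteringResult", function(object) {
  if (any(object@labels < 0L | object@labels >= object@k))
    return("labels must lie in [0, k)")
  if (abs(sum(object@populationFraction) - 1) > 1e-9)
    return("population fractions must sum to 1")
  TRUE
})

#' Sweep of clusterings over a range of cluster counts
#'
#' @slot results list of \code{ClusteringResult}, one per k.
#' @slot selectedK integer.
#' @slot selectionRule character ("psf-max", "dbi-min" or "manual").
#' @exportClass KSweepReport
setClass("KSweepReport",
  representation(results = "list", selectedK = "integer",
                 selectionRule = "character")
)

#' Fixed grid region within which per-frame pocket volume is counted
#'
#' @slot origin numeric length-3; grid origin (Angstrom).
#' @slot spacing numeric; grid spacing (Angstrom).
#' @slot dims integer length-3; grid point counts per axis.
#' @slot includedIdx integer; linear indices (1-based, column-major) of grid
#'   points inside the envelope.
#' @slot refAnchorCoords matrix; cage anchor coordinates of the first open
#'   reference, the frame all measured structures are superposed onto.
#' @slot cageSpec \code{CageSpec} used to build the envelope.
#' @slot provenance list; reference ids and construction parameters.
#' @exportClass PocketEnvelope
setClass("PocketEnvelope",
  representation(origin = "numeric", spacing = "numeric", dims = "integer",
                 includedIdx = "integer", refAnchorCoords = "matrix",
                 cageSpec = "CageSpec", provenance = "list")
)

setValidity("PocketEnvelope", function(object) {
  if (length(object@includedIdx) == 0) return("envelope must be non-empty")
  if (object@spacing <= 0) return("spacing must be positive")
  TRUE
})

#' Van der Waals radii and probe radius for occupancy tests
#'
#' @slot radii named numeric; element -> vdW radius (Angstrom).
#' @slot defaultRadius numeric; radius for elements not in the table.
#' @slot probeRadius numeric; solvent probe radius (Angstrom).
#' @exportClass RadiiTable
setClass("RadiiTable",
  representation(radii = "numeric", defaultRadius = "numeric",
                 probeRadius = "numeric")
)

setValidity("RadiiTable", function(object) {
  if (any(object@radii <= 0) || object@defaultRadius <= 0 ||
      object@probeRadius < 0)
    return("radii must be positive and probe radius non-negative")
  TRUE
})

#' Synthetic cage template with named conformational states
#'
#' @slot topology \code{CageStructure}; shared topology (backbone, side
#'   chains, enclosing scaffold shell).
#' @slot states named list of coordinate matrices (n_atoms x 3), one per
#'   state (default closed/open1/open2/collapsed).
#' @slot designedGaps numeric matrix; pairwise side-chain RMSD between states,
#'   computed (not assumed) at construction.
#' @slot keyDistances named numeric; key atom pair distance per state.
#' @slot cavitySpec list(center, radius); analytic cavity present only in
#'   open states.
#' @slot cageSpec \code{CageSpec} for the template.
#' @slot seed integer used for construction.
#' @exportClass CageTemplate
setClass("CageTemplate",
  representation(topology = "CageStructure", states = "list",
                 designedGaps = "matrix", keyDistances = "numeric",
                 cavitySpec = "list", cageSpec = "CageSpec", seed = "integer")
)

setValidity("CageTemplate", function(object) {
  if (is.null(names(object@states)) || anyDuplicated(names(object@states)))
    return("states must be uniquely named")
  n <- nrow(object@topology@atoms)
  ok <- vapply(object@states, function(s) {
    is.matrix(s) && nrow(s) == n && ncol(s) == 3
  }, logical(1))
  if (!all(ok)) return("every state must be an n_atoms x 3 matrix")
  TRUE
})
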