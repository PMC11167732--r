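## Deriving named reference states from a crystal-structure ensemble by
## threshold clustering of the side-chain RMSD matrix, and classifying
## arbitrary conformers against them.

#' Threshold clustering of an RMSD matrix
#'
#' Builds the graph whose edges connect structure pairs with RMSD strictly
#' below the threshold and returns its connected components
#' (single-linkage). Components of size 1 are reported as singletons, the
#' situation of a crystal structure that cannot be assigned to any cluster
#' of similar cage conformations.
#'
#' @param m an \code{RMSDMatrix}.
#' @param threshold Angstrom; edges require RMSD < threshold.
#' @return list with \code{clusters} (list of character id vectors, each of
#'   size >= 2, ordered by first appearance), \code{singletons} (character
#'   ids) and \code{exemplars} (medoid id per cluster: minimum summed RMSD
#'   to the cluster's members, ties broken by matrix order).
#' @export
thresholdCluster <- function(m, threshold) {
  stopifnot(is(m, "RMSDMatrix"))
  if (threshold <= 0) stop("threshold must be positive")
  v <- m@values
  n <- nrow(v)
  if (n == 0) stop("empty RMSD matrix")
  adj <- v < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(seq_len(n), comp)
  ## order components by their first member so output is input-order stable
  groups <- groups[order(vapply(groups, min, integer(1)))]
  clusters <- list(); singles <- character(0); exemplars <- character(0)
  for (idx in groups) {
    if (length(idx) == 1) {
      singles <- c(singles, m@labels[idx])
    } else {
      sums <- rowSums(v[idx, idx, drop = FALSE])
      med <- idx[which.min(sums)]
      clusters[[length(clusters) + 1]] <- m@labels[idx]
      exemplars <- c(exemplars, m@labels[med])
    }
  }
  list(clusters = clusters, singletons = singles, exemplars = exemplars)
}

#' Build a reference library from a structure ensemble
#'
#' Threshold-clusters the ensemble's side-chain RMSD matrix and creates one
#' named \code{ReferenceState} per cluster. The default exemplar is the
#' cluster medoid; \code{manualPicks} overrides it for curated choices (the
#' typical usage: one apo and one inhibitor-bound reference). Singletons
#' become one-member states when \code{includeSingletons}.
#'
#' @param structures list of \code{CageStructure} (>= 2).
#' @param spec a \code{CageSpec}.
#' @param threshold Angstrom (default: the spec's threshold).
#' @param manualPicks optional named character vector
#'   \code{c(stateName = structureId, ...)}; each id must be present in the
#'   ensemble, and replaces the medoid of the cluster containing it. Ids not
#'   inside any cluster (singletons) become their own states.
#' @param stateNames optional character; names for the clusters in output
#'   order (default state1, state2, ... / singleton ids).
#' @param includeSingletons logical; promote singletons to states.
#' @param measureDescriptors logical; record the exemplar key distance.
#' @return A \code{ReferenceLibrary}.
#' @export
buildLibrary <- function(structures, spec, threshold = spec@threshold,
                         manualPicks = NULL, stateNames = NULL,
                         includeSingletons = TRUE,
                         measureDescriptors = TRUE) {
  if (length(structures) < 2) stop("need at least 2 structures")
  ids <- vapply(structures, structureId, character(1))
  if (!is.null(manualPicks)) {
    absent <- setdiff(unname(manualPicks), ids)
    if (length(absent))
      stop("manual pick(s) absent from inputs: ",
           paste(absent, collapse = ", "))
  }
  m <- rmsdMatrix(structures, spec)
  tc <- thresholdCluster(m, threshold)
  states <- list()
  addState <- function(name, exemplar_id, member_ids) {
    s <- structures[[match(exemplar_id, ids)]]
    desc <- c(keyDistance = NA_real_, pocketVolume = NA_real_)
    if (measureDescriptors) {
      sel <- resolveSelection(s, spec)
      desc["keyDistance"] <- atomPairDistance(s, sel@keyPairIdx)
    }
    states[[length(states) + 1]] <<- new("ReferenceState", name = name,
      exemplar = s, memberIds = member_ids, descriptors = desc)
  }
  for (ci in seq_along(tc$clusters)) {
    members <- tc$clusters[[ci]]
    ex <- tc$exemplars[ci]
    if (!is.null(manualPicks)) {
      hit <- manualPicks[manualPicks %in% members]
      if (length(hit)) ex <- unname(hit[1])
    }
    nm <- if (!is.null(stateNames) && ci <= length(stateNames))
            stateNames[ci] else paste0("state", ci)
    addState(nm, ex, members)
  }
  if (includeSingletons) {
    for (sid in tc$singletons) {
      nm <- sid
      if (!is.null(manualPicks) && sid %in% manualPicks)
        nm <- names(manualPicks)[match(sid, manualPicks)]
      else if (!is.null(stateNames)) {
        used <- length(tc$clusters) + match(sid, tc$singletons)
        if (used <= length(stateNames)) nm <- stateNames[used]
      }
      addState(nm, sid, sid)
    }
  }
  ## manual picks may also rename cluster states
  if (!is.null(manualPicks) && !is.null(names(manualPicks))) {
    for (j in seq_along(states)) {
      hit <- match(states[[j]]@exemplar@id, manualPicks)
      if (!is.na(hit) && nzchar(names(manualPicks)[hit]))
        states[[j]]@name <- names(manualPicks)[hit]
    }
  }
  obj <- new("ReferenceLibrary", states = states, threshold = threshold,
             cageSpec = spec)
  validObject(obj)
  obj
}

#' Classify a conformer against a reference library
#'
#' Computes the side-chain RMSD to every state exemplar; the label is the
#' closest state if its RMSD is strictly below the library threshold,
#' otherwise "novel". Ties break toward the earlier state in library order.
#'
#' @param conformer a \code{CageStructure} resolving the library's cage
#'   spec.
#' @param library a \code{ReferenceLibrary}.
#' @return A \code{StateAssignment}.
#' @export
classifyConformer <- function(conformer, library) {
  stopifnot(is(library, "ReferenceLibrary"))
  nm <- stateNames(library)
  r <- vapply(library@states, function(s)
    sidechainRMSD(conformer, s@exemplar, library@cageSpec), numeric(1))
  names(r) <- nm
  best <- which.min(r)  # first minimum on ties
  label <- if (r[best] < library@threshold) nm[best] else "novel"
  new("StateAssignment", label = label, rmsdToEach = r)
}

#' Serialize a reference library to JSON (+ exemplar PDB files)
#'
#' @param library a \code{ReferenceLibrary}.
#' @param dir output directory; created if needed.
#' @return The JSON path, invisibly.
#' @export
writeLibrary <- function(library, dir) {
  stopifnot(is(library, "ReferenceLibrary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  states <- lapply(library@states, function(s) {
    pdb <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", s@name),
                                 ".pdb"))
    writePDB(s@exemplar, pdb)
    list(name = s@name, exemplar = s@exemplar@id,
         members = as.list(s@memberIds),
         descriptors = as.list(s@descriptors),
         exemplar_pdb = basename(pdb))
  })
  path <- file.path(dir, "library.json")
  jsonlite::write_json(list(threshold = library@threshold, states = states),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
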