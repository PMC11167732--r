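## Reading/writing PDB structures and multi-model trajectories, and
## resolving cage definitions into atom index sets. Coordinate parsing is
## delegated to bio3d; a light pre-scan enforces this package's error
## contracts (line-numbered parse errors, per-model atom counts) before
## bio3d sees the file.

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

#' Construct a cage specification
#'
#' @param residues data.frame with columns \code{chain}, \code{resNum},
#'   \code{resName} (one row per cage residue), or a list of
#'   \code{c(chain, resNum, resName)} triples.
#' @param keyPair list of two \code{c(chain, resNum, atomName)} triples (or a
#'   2-row data.frame): the atom pair whose distance tracks cage opening.
#' @param anchorAtoms atom names used as superposition anchors.
#' @param sidechainExclusions backbone atom names excluded from the
#'   side-chain heavy-atom set. Hydrogens are always excluded.
#' @param threshold assignment threshold in Angstrom; a conformation within
#'   this side-chain RMSD of a reference exemplar counts as that state.
#' @return A \code{CageSpec}.
#' @examples
#' spec <- cageSpec(
#'   residues = list(c("A", 62, "TRP"), c("A", 72, "TRP"), c("A", 91, "TYR"),
#'                   c("A", 98, "TYR"), c("A", 251, "PHE")),
#'   keyPair = list(c("A", 72, "CH2"), c("A", 251, "CG")))
#' @export
cageSpec <- function(residues, keyPair, anchorAtoms = "CA",
                     sidechainExclusions = BACKBONE_NAMES,
                     threshold = 1.2) {
  if (is.list(residues) && !is.data.frame(residues)) {
    residues <- do.call(rbind, lapply(residues, function(r)
      data.frame(chain = as.character(r[1]), resNum = as.integer(r[2]),
                 resName = as.character(r[3]), stringsAsFactors = FALSE)))
  }
  residues$resNum <- as.integer(residues$resNum)
  if (is.list(keyPair) && !is.data.frame(keyPair)) {
    keyPair <- do.call(rbind, lapply(keyPair, function(r)
      data.frame(chain = as.character(r[1]), resNum = as.integer(r[2]),
                 atomName = as.character(r[3]), stringsAsFactors = FALSE)))
  }
  keyPair$resNum <- as.integer(keyPair$resNum)
  obj <- new("CageSpec", residues = residues, anchorAtoms = anchorAtoms,
             sidechainExclusions = sidechainExclusions, keyPair = keyPair,
             threshold = threshold)
  validObject(obj)
  obj
}

#' Read a cage specification from a YAML config block
#'
#' Expects keys \code{residues} (list of \code{[chain, resNum, resName]}),
#' \code{key_pair} (two \code{[chain, resNum, atomName]} entries) and
#' optionally \code{anchor_atoms}, \code{sidechain_exclusions},
#' \code{threshold}.
#'
#' @param path YAML file, or a list already parsed from one.
#' @return A \code{CageSpec}.
#' @export
readCageSpec <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg$residues)) stop("cage spec is missing 'residues'")
  if (is.null(cfg$key_pair)) stop("cage spec is missing 'key_pair'")
  cageSpec(
    residues = cfg$residues,
    keyPair = cfg$key_pair,
    anchorAtoms = if (!is.null(cfg$anchor_atoms)) unlist(cfg$anchor_atoms)
                  else "CA",
    sidechainExclusions = if (!is.null(cfg$sidechain_exclusions))
                            unlist(cfg$sidechain_exclusions)
                          else BACKBONE_NAMES,
    threshold = if (!is.null(cfg$threshold)) cfg$threshold else 1.2
  )
}

## Scan raw PDB lines: validate coordinate fields on ATOM/HETATM records and
## return the line numbers belonging to each MODEL block (one block for
## single-model files).
scanPdbLines <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in '", path, "'")
  bad <- which(is_atom & nchar(lines) < 54)
  coord_txt <- substring(lines[is_atom], 31, 54)
  xs <- suppressWarnings(as.numeric(substr(coord_txt, 1, 8)))
  ys <- suppressWarnings(as.numeric(substr(coord_txt, 9, 16)))
  zs <- suppressWarnings(as.numeric(substr(coord_txt, 17, 24)))
  bad <- sort(unique(c(bad, which(is_atom)[is.na(xs) | is.na(ys) | is.na(zs)])))
  if (length(bad))
    stop("malformed coordinate fields in '", path, "' at line ", bad[1])
  model_starts <- which(substr(lines, 1, 5) == "MODEL")
  if (length(model_starts) == 0) {
    blocks <- list(which(is_atom))
  } else {
    model_ends <- which(substr(lines, 1, 6) == "ENDMDL")
    if (length(model_ends) < length(model_starts))
      model_ends <- c(model_ends, length(lines))
    blocks <- lapply(seq_along(model_starts), function(i) {
      idx <- seq(model_starts[i], model_ends[i])
      idx[is_atom[idx]]
    })
  }
  blocks
}

## bio3d atom table (possibly with alt-loc duplicates) -> this package's
## atom data.frame with the alt-loc policy applied: within each
## (chain, resNum, name) group keep the highest-occupancy record, ties
## broken alphabetically by alt-loc id.
bio3dToAtoms <- function(at) {
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  elesy <- ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                  substr(trimws(at$elety), 1, 1), trimws(at$elesy))
  df <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = elesy,
    resName = trimws(at$resid), resNum = at$resno,
    chain = ifelse(is.na(at$chain), "", at$chain),
    x = at$x, y = at$y, z = at$z, altLoc = alt,
    hetatm = at$type == "HETATM", occ = occ,
    stringsAsFactors = FALSE
  )
  key <- paste(df$chain, df$resNum, df$name, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(ix) {
    if (length(ix) == 1) return(ix)
    sub <- df[ix, ]
    best <- ix[sub$occ == max(sub$occ)]
    if (length(best) > 1) best <- best[order(df$altLoc[best])]
    best[1]
  }), use.names = FALSE)
  df <- df[sort(keep), setdiff(names(df), "occ")]
  rownames(df) <- NULL
  df
}

#' Read a PDB structure
#'
#' All ATOM records of the first model are returned; HETATM records are
#' retained and flagged in the \code{hetatm} column. Alternate locations are
#' collapsed to the highest-occupancy record (ties broken alphabetically, so
#' equal occupancies keep alt-loc 'A').
#'
#' @param path path to a fixed-column PDB file.
#' @param id structure id; defaults to the file base name.
#' @return A \code{CageStructure}.
#' @export
readPDB <- function(path, id = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  scanPdbLines(lines, path)  # validates; stops on malformed records
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  atoms <- bio3dToAtoms(pdb$atom)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  obj <- new("CageStructure", id = id, atoms = atoms)
  validObject(obj)
  obj
}

#' Read a trajectory from a multi-model PDB file
#'
#' Frames are returned in file order; no superposition is applied on read.
#'
#' @param path multi-model PDB file (MODEL/ENDMDL blocks).
#' @param topology optional \code{CageStructure} giving the atom ordering
#'   authority; defaults to model 1 of the file. If supplied, every model's
#'   atom count must match it.
#' @return A \code{CageTrajectory}.
#' @export
readTrajectory <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  blocks <- scanPdbLines(lines, path)
  counts <- lengths(blocks)
  n_ref <- if (!is.null(topology)) nrow(topology@atoms) else counts[1]
  bad <- which(counts != n_ref)
  if (length(bad))
    stop("atom count mismatch in '", path, "': frame ", bad[1], " has ",
         counts[bad[1]], " atoms, expected ", n_ref)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  if (is.null(topology)) {
    atoms <- bio3dToAtoms(pdb$atom)
    topology <- new("CageStructure",
                    id = sub("\\.(pdb|ent)$", "", basename(path)),
                    atoms = atoms)
    validObject(topology)
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3
  if (n_atoms != nrow(topology@atoms))
    stop("trajectory atom count (", n_atoms,
         ") does not match topology (", nrow(topology@atoms), ")")
  arr <- array(0, dim = c(n_atoms, 3, n_frames))
  for (f in seq_len(n_frames))
    arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  obj <- new("CageTrajectory", topology = topology, coords = arr)
  validObject(obj)
  obj
}

formatAtomLine <- function(serial, name, resName, chain, resNum, xyz,
                           element, hetatm = FALSE, altLoc = "") {
  rec <- ifelse(hetatm, "HETATM", "ATOM  ")
  nm <- ifelse(nchar(name) < 4, sprintf(" %-3s", name),
               sprintf("%-4s", name))
  sprintf("%s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial %% 100000, nm, altLoc, resName, chain, resNum %% 10000,
          xyz[1], xyz[2], xyz[3], 1, 0, element)
}

structureLines <- function(structure, xyz = NULL) {
  a <- structure@atoms
  if (is.null(xyz)) xyz <- coords(structure)
  vapply(seq_len(nrow(a)), function(i)
    formatAtomLine(a$serial[i], a$name[i], a$resName[i], a$chain[i],
                   a$resNum[i], xyz[i, ], a$element[i], a$hetatm[i],
                   a$altLoc[i]),
    character(1))
}

#' Write a structure to a PDB file
#'
#' @param structure a \code{CageStructure}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePDB <- function(structure, path) {
  stopifnot(is(structure, "CageStructure"))
  writeLines(c(structureLines(structure), "END"), path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param trajectory a \code{CageTrajectory}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(trajectory, path) {
  stopifnot(is(trajectory, "CageTrajectory"))
  n <- nFrames(trajectory)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(structureLines(trajectory@topology, frameCoords(trajectory, f)),
               con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

isHydrogen <- function(atoms) {
  el <- toupper(trimws(atoms$element))
  el %in% c("H", "D") | grepl("^[0-9]*H", toupper(atoms$name))
}

#' Resolve a cage specification into atom index sets on one structure
#'
#' The anchor set contains one anchor atom (C-alpha by default) per cage
#' residue in spec order; the side-chain set contains the heavy atoms of the
#' cage residues minus the backbone exclusions, ordered canonically by
#' (spec residue order, atom name) so that selections resolved on different
#' structures correspond atom by atom.
#'
#' @param structure a \code{CageStructure}.
#' @param spec a \code{CageSpec}.
#' @return An \code{AtomIndexSets}.
#' @export
resolveSelection <- function(structure, spec) {
  stopifnot(is(structure, "CageStructure"), is(spec, "CageSpec"))
  a <- structure@atoms
  hyd <- isHydrogen(a)
  missing <- character(0)
  anchor <- integer(0)
  side <- integer(0)
  res <- spec@residues
  for (i in seq_len(nrow(res))) {
    in_res <- a$chain == res$chain[i] & a$resNum == res$resNum[i] & !a$hetatm
    if (!any(in_res)) {
      missing <- c(missing, sprintf("%s/%s%d", res$chain[i], res$resName[i],
                                    res$resNum[i]))
      next
    }
    anc <- which(in_res & a$name %in% spec@anchorAtoms)
    if (length(anc) == 0)
      missing <- c(missing, sprintf("%s/%s%d anchor (%s)", res$chain[i],
                                    res$resName[i], res$resNum[i],
                                    paste(spec@anchorAtoms, collapse = "/")))
    anchor <- c(anchor, anc[1])
    sc <- which(in_res & !hyd &
                !(a$name %in% spec@sidechainExclusions) &
                !(a$name %in% spec@anchorAtoms))
    side <- c(side, sc[order(a$name[sc])])
  }
  kp <- spec@keyPair
  key_idx <- vapply(1:2, function(j) {
    hit <- which(a$chain == kp$chain[j] & a$resNum == kp$resNum[j] &
                 a$name == kp$atomName[j])
    if (length(hit) == 0) {
      missing <<- c(missing, sprintf("%s/%d-%s", kp$chain[j], kp$resNum[j],
                                     kp$atomName[j]))
      return(NA_integer_)
    }
    hit[1]
  }, integer(1))
  if (length(missing))
    stop("cannot resolve cage selection on '", structure@id, "': missing ",
         paste(missing, collapse = ", "))
  obj <- new("AtomIndexSets", anchorIdx = as.integer(anchor),
             sidechainIdx = as.integer(side),
             keyPairIdx = as.integer(key_idx))
  validObject(obj)
  obj
}
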