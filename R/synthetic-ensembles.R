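## Synthetic stand-in crystal ensembles. These emulate the published
## reference-ensemble structure of two methyl-reader systems (a tandem
## Tudor-domain reader with two druggable cages and a single Tudor-domain
## reader): residue rosters, key atom pairs, the designed key-pair
## distances of the curated open/closed reference states, the cluster
## composition of the deposited ensembles (two clusters plus one
## unassignable entry / three conformational groups) and the qualitative
## pocket-volume orderings. All coordinates are synthetic generator output,
## NOT deposited crystal coordinates; ids carry a "SYN" prefix to make that
## unmistakable.

referenceSystemPresets <- function() list(
  "SPIN1-domain1" = list(
    residues = data.frame(chain = "A",
                          resNum = c(62L, 72L, 91L, 98L, 251L),
                          resName = c("TRP", "TRP", "TYR", "TYR", "PHE"),
                          stringsAsFactors = FALSE),
    keyResidueIdx = c(2L, 5L),            # W72 tip vs F251 CG
    keyPairAtoms = c("CH2", "CG"),
    statePoses = list(closed = list(tilt = 13, twist = 15, spread = 75),
                      open1 = list(tilt = 58, twist = 90, spread = 10),
                      open2 = list(tilt = 58, twist = -90, spread = -10)),
    keyDistanceTargets = c(closed = 6.0, open1 = 9.5, open2 = 8.9),
    clusterSizes = c(closed = 12L, open1 = 6L, open2 = 1L),
    verifyVolume = TRUE),
  "SPIN1-domain2" = list(
    residues = data.frame(chain = "A",
                          resNum = c(141L, 151L, 170L, 177L),
                          resName = c("PHE", "TRP", "TYR", "TYR"),
                          stringsAsFactors = FALSE),
    keyResidueIdx = c(1L, 4L),            # F141 tip vs Y177 CG
    keyPairAtoms = c("CZ", "CG"),
    ## the closed cage of this domain keeps a residual (ligandable) pocket,
    ## hence a partially open closed-state pose
    statePoses = list(closed = list(tilt = 34, twist = 15, spread = 75),
                      open1 = list(tilt = 58, twist = 90, spread = 10)),
    keyDistanceTargets = c(closed = 6.7, open1 = 10.5),
    clusterSizes = c(closed = 13L, open1 = 6L),
    verifyVolume = FALSE),
  "SMN-Tudor" = list(
    residues = data.frame(chain = "A",
                          resNum = c(102L, 109L, 127L, 130L),
                          resName = c("TRP", "TYR", "TYR", "TYR"),
                          stringsAsFactors = FALSE),
    keyResidueIdx = c(1L, 4L),            # W102 tip vs Y130 CG
    keyPairAtoms = c("CH2", "CG"),
    ## two open states of increasing openness -> increasing pocket volume
    statePoses = list(closed = list(tilt = 13, twist = 15, spread = 75),
                      open1 = list(tilt = 48, twist = 90, spread = 10),
                      open2 = list(tilt = 62, twist = -90, spread = -10)),
    keyDistanceTargets = c(closed = 4.8, open1 = 7.0, open2 = 7.6),
    clusterSizes = c(closed = 2L, open1 = 3L, open2 = 1L),
    minKeyGap = 2.0, verifyVolume = TRUE)
)

#' Synthetic stand-in reference ensemble for one reader-domain system
#'
#' Generates a synthetic crystal-structure ensemble emulating a named
#' aromatic-cage system: the curated reference states carry exactly the
#' designed key-atom-pair distances, cluster membership mirrors the
#' published ensemble composition (including an unassignable singleton
#' state where one exists), and open-state pocket volumes are ordered by
#' designed openness. Every structure id is prefixed "SYN": these are
#' generator coordinates, not deposited crystal structures.
#'
#' @param system one of "SPIN1-domain1", "SPIN1-domain2", "SMN-Tudor".
#' @param seed integer; the whole ensemble is deterministic per seed.
#' @param noiseSigma per-coordinate Gaussian noise (A) applied to the
#'   non-reference ensemble members (default 0.25, small against the
#'   inter-state contrasts).
#' @return list with \code{structures} (the full ensemble, references
#'   included), \code{references} (named character: state -> structure id),
#'   \code{spec} (the system's \code{CageSpec}), \code{template} (the
#'   underlying \code{CageTemplate}) and \code{system}.
#' @export
syntheticReferenceEnsemble <- function(system = c("SPIN1-domain1",
                                                  "SPIN1-domain2",
                                                  "SMN-Tudor"),
                                       seed = 1, noiseSigma = 0.25) {
  system <- match.arg(system)
  p <- referenceSystemPresets()[[system]]
  template <- makeTemplate(
    nRes = nrow(p$residues), seed = seed, residues = p$residues,
    statePoses = p$statePoses, keyDistanceTargets = p$keyDistanceTargets,
    keyResidueIdx = p$keyResidueIdx, keyPairAtoms = p$keyPairAtoms,
    minKeyGap = if (!is.null(p$minKeyGap)) p$minKeyGap else 2.5,
    verifyVolume = p$verifyVolume)
  tag <- toupper(gsub("[^A-Za-z0-9]", "", system))
  structures <- list(); references <- character(0)
  withSeed(seed * 977L + 13L, {
    for (state in names(p$clusterSizes)) {
      n_members <- p$clusterSizes[[state]]
      ref <- stateStructure(template, state)
      ref@id <- sprintf("SYN-%s-%s-ref", tag, state)
      structures[[length(structures) + 1L]] <- ref
      references[state] <- ref@id
      if (n_members > 1) {
        base <- template@states[[state]]
        for (m in seq_len(n_members - 1L)) {
          xyz <- base + matrix(stats::rnorm(length(base),
                                            sd = noiseSigma),
                               nrow(base), 3)
          R <- rotationAboutAxis(stats::rnorm(3),
                                 stats::runif(1, 0, 2 * pi))
          xyz <- sweep(tcrossprod(xyz, R), 2, -stats::runif(3, -5, 5))
          st <- setCoords(template@topology, xyz)
          st@id <- sprintf("SYN-%s-%s-m%02d", tag, state, m)
          structures[[length(structures) + 1L]] <- st
        }
      }
    }
  })
  list(structures = structures, references = references,
       spec = template@cageSpec, template = template, system = system)
}
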