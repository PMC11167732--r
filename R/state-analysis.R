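## Descriptor time series (key distance, pocket volume), kernel-density
## summaries with peak detection, and the per-trajectory state report that
## assembles clustering, classification and descriptors into one bundle.

#' Per-frame descriptor series
#'
#' Key atom pair distance (rigid-motion invariant, measured on the raw
#' frame) and pocket volume (after internal superposition onto the
#' envelope's reference frame) per strided frame.
#'
#' @param trajectory a \code{CageTrajectory}.
#' @param spec a \code{CageSpec}.
#' @param envelope optional \code{PocketEnvelope}; without it the volume
#'   column is NA.
#' @param stride keep every stride-th frame.
#' @param radii a \code{RadiiTable}.
#' @return data.frame with columns \code{frame}, \code{keyDistance},
#'   \code{volume}.
#' @export
descriptorSeries <- function(trajectory, spec, envelope = NULL,
                             stride = 1L, radii = defaultRadii()) {
  stopifnot(is(trajectory, "CageTrajectory"), is(spec, "CageSpec"))
  sel <- resolveSelection(trajectory@topology, spec)
  frames <- seq(1L, nFrames(trajectory), by = as.integer(stride))
  keyd <- vapply(frames, function(f)
    atomPairDistance(frameCoords(trajectory, f), sel@keyPairIdx),
    numeric(1))
  vol <- rep(NA_real_, length(frames))
  if (!is.null(envelope))
    vol <- volumeSeries(trajectory, envelope, radii = radii,
                        frames = frames)$volume
  data.frame(frame = as.integer(frames), keyDistance = keyd, volume = vol)
}

#' Gaussian kernel density summary with peak detection
#'
#' Density on an even grid spanning [min - 3h, max + 3h]; peaks are local
#' maxima above 5 percent of the global maximum. The default "hybrid"
#' bandwidth is the geometric mean of the Sheather-Jones plug-in and the
#' Silverman normal-reference bandwidths: the plug-in rule alone keeps
#' multimodal descriptor data resolved but makes mode locations noisy at a
#' few hundred observations, while the normal-reference rules oversmooth
#' mixtures until nearby modes merge; their geometric mean keeps
#' well-separated modes resolved with stable peak locations.
#'
#' @param values numeric vector (>= 2 finite values).
#' @param bandwidth "hybrid" (default), "sj" (Sheather-Jones), "scott",
#'   "silverman", or a numeric bandwidth in data units.
#' @return list with \code{grid}, \code{density}, \code{bandwidth},
#'   \code{peaks} (descriptor values at the detected modes) and
#'   \code{degenerate} (TRUE for an all-identical point mass, where the
#'   density is not estimable).
#' @export
kdeDensity <- function(values, bandwidth = "hybrid") {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 finite values")
  if (max(values) == min(values))
    return(list(grid = values[1], density = Inf, bandwidth = 0,
                peaks = values[1], degenerate = TRUE))
  h <- if (is.numeric(bandwidth)) bandwidth
       else switch(match.arg(bandwidth,
                             c("hybrid", "sj", "scott", "silverman")),
                   hybrid = sqrt(stats::bw.SJ(values) *
                                 stats::bw.nrd0(values)),
                   sj = stats::bw.SJ(values),
                   scott = stats::bw.nrd(values),
                   silverman = stats::bw.nrd0(values))
  d <- stats::density(values, bw = h, from = min(values) - 3 * h,
                      to = max(values) + 3 * h, n = 512)
  y <- d$y
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                      y[2:(n - 1)] >= y[3:n], FALSE) &
             y >= 0.05 * max(y)
  list(grid = d$x, density = y, bandwidth = h, peaks = d$x[is_peak],
       degenerate = FALSE)
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Full per-trajectory state report
#'
#' Runs the complete analysis: frame distance matrix on the side-chain RMSD
#' metric, cluster-count sweep, per-cluster descriptor summary with medoid
#' classification, descriptor series and kernel-density summaries, and the
#' verdict listing which reference states were sampled (a state counts as
#' sampled when some cluster medoid lies within the library threshold of
#' its exemplar). When \code{outDir} is given, the bundle (report.json,
#' clusters.tsv, descriptors.tsv, density.tsv, sweep.json, medoid PDBs) is
#' written there; regeneration from identical inputs is byte-identical.
#'
#' @param trajectory a \code{CageTrajectory}.
#' @param spec a \code{CageSpec}.
#' @param library a \code{ReferenceLibrary}.
#' @param envelope optional \code{PocketEnvelope}.
#' @param kMin,kMax cluster-count sweep range.
#' @param stride clustering/descriptor stride.
#' @param rule cluster-count selection rule (see \code{\link{sweepK}}).
#' @param manualK k for the "manual" rule.
#' @param radii a \code{RadiiTable}.
#' @param outDir optional output directory for the report bundle.
#' @return list with \code{verdict}, \code{selectedK}, \code{sweep},
#'   \code{clusters} (data.frame), \code{descriptors} (data.frame),
#'   \code{distanceDensity}, \code{volumeDensity}.
#' @export
stateReport <- function(trajectory, spec, library, envelope = NULL,
                        kMin = 2L, kMax = 20L, stride = 1L,
                        rule = "psf-max", manualK = NULL,
                        radii = defaultRadii(), outDir = NULL) {
  stopifnot(is(trajectory, "CageTrajectory"), is(library,
            "ReferenceLibrary"))
  fdm <- withStage("distance-matrix",
                   frameDistanceMatrix(trajectory, spec, stride = stride))
  sweep_rep <- withStage("k-sweep",
                         sweepK(fdm, kMin = kMin, kMax = kMax, rule = rule,
                                manualK = manualK))
  best <- sweep_rep@results[[paste0("k", sweep_rep@selectedK)]]
  clusters <- withStage("cluster-summary",
                        clusterSummary(trajectory, best, spec,
                                       envelope = envelope,
                                       library = library, radii = radii))
  descriptors <- withStage("descriptors",
                           descriptorSeries(trajectory, spec,
                                            envelope = envelope,
                                            stride = stride,
                                            radii = radii))
  dist_dens <- withStage("density",
                         kdeDensity(descriptors$keyDistance))
  vol_dens <- if (!is.null(envelope) && !all(is.na(descriptors$volume)))
    withStage("density", kdeDensity(descriptors$volume)) else NULL
  rmsd_cols <- grep("^rmsd_", names(clusters), value = TRUE)
  verdict <- character(0)
  for (col in rmsd_cols) {
    state <- sub("^rmsd_", "", col)
    if (any(clusters[[col]] < library@threshold))
      verdict <- c(verdict, state)
  }
  out <- list(verdict = verdict, selectedK = sweep_rep@selectedK,
              sweep = sweep_rep, clusters = clusters,
              descriptors = descriptors, distanceDensity = dist_dens,
              volumeDensity = vol_dens)
  if (!is.null(outDir)) writeReportBundle(out, trajectory, outDir)
  out
}

writeReportBundle <- function(report, trajectory, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
    utils::write.table(df, file.path(outDir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(report$clusters, "clusters.tsv")
  tsv(report$descriptors, "descriptors.tsv")
  dd <- data.frame(value = report$distanceDensity$grid,
                   distanceDensity = report$distanceDensity$density)
  tsv(dd, "density.tsv")
  writeSweepReport(report$sweep, file.path(outDir, "sweep.json"))
  best_frames <- report$clusters$medoidFrame
  for (i in seq_along(best_frames)) {
    st <- setCoords(trajectory@topology,
                    frameCoords(trajectory, best_frames[i]))
    st@id <- sprintf("cluster%d-medoid", report$clusters$cluster[i])
    writePDB(st, file.path(outDir, sprintf("medoid-cluster%d.pdb",
                                           report$clusters$cluster[i])))
  }
  jsonlite::write_json(
    list(verdict = report$verdict,
         selected_k = report$selectedK,
         selection_rule = report$sweep@selectionRule,
         n_frames_clustered = length(report$sweep@results[[1]]@labels),
         clusters = report$clusters,
         distance_peaks = report$distanceDensity$peaks,
         volume_peaks = if (!is.null(report$volumeDensity))
           report$volumeDensity$peaks else NULL),
    file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, dataframe = "rows", na = "null")
  invisible(outDir)
}

#' Build a reference library directly from curated exemplars
#'
#' The curated counterpart of \code{\link{buildLibrary}}: one state per
#' supplied structure, in the given order, with measured key-distance
#' descriptors.
#'
#' @param structures list of \code{CageStructure} exemplars.
#' @param names state names, one per structure.
#' @param spec a \code{CageSpec}.
#' @param threshold assignment threshold (default: the spec's).
#' @param envelope optional \code{PocketEnvelope} to record exemplar pocket
#'   volumes.
#' @param radii a \code{RadiiTable}.
#' @return A \code{ReferenceLibrary}.
#' @export
libraryFromExemplars <- function(structures, names, spec,
                                 threshold = spec@threshold,
                                 envelope = NULL, radii = defaultRadii()) {
  if (length(structures) != length(names))
    stop("one name per exemplar required")
  states <- lapply(seq_along(structures), function(i) {
    s <- structures[[i]]
    sel <- resolveSelection(s, spec)
    desc <- c(keyDistance = atomPairDistance(s, sel@keyPairIdx),
              pocketVolume = if (!is.null(envelope))
                frameVolume(s, envelope, radii = radii) else NA_real_)
    new("ReferenceState", name = names[i], exemplar = s,
        memberIds = s@id, descriptors = desc)
  })
  obj <- new("ReferenceLibrary", states = states, threshold = threshold,
             cageSpec = spec)
  validObject(obj)
  obj
}
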