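## Hierarchical agglomerative clustering of trajectory frames on the
## side-chain RMSD metric, cluster-count selection via validity indices
## (Davies-Bouldin, pseudo-F, SSR/SST in medoid form), and per-cluster
## descriptor summaries.

#' Pairwise side-chain RMSD matrix over (strided) trajectory frames
#'
#' The trajectory is prealigned once: every frame is superposed onto frame 1
#' using the cage anchor atoms, and pairwise side-chain RMSDs are then
#' computed without re-fitting (the package-wide superposition convention).
#'
#' @param trajectory a \code{CageTrajectory}.
#' @param spec a \code{CageSpec} resolving on the trajectory topology.
#' @param stride keep every stride-th frame (default 1).
#' @return A \code{FrameDistanceMatrix}.
#' @export
frameDistanceMatrix <- function(trajectory, spec, stride = 1L) {
  stopifnot(is(trajectory, "CageTrajectory"), is(spec, "CageSpec"))
  if (stride < 1) stop("stride must be >= 1")
  sel <- resolveSelection(trajectory@topology, spec)
  n <- nFrames(trajectory)
  frames <- seq(1L, n, by = as.integer(stride))
  if (length(frames) < 2) stop("fewer than 2 strided frames")
  aligned <- alignTrajectory(trajectory, sel@anchorIdx, refFrame = 1)
  m <- length(sel@sidechainIdx)
  X <- t(vapply(frames, function(f)
    as.numeric(aligned@coords[sel@sidechainIdx, , f]), numeric(3 * m)))
  d <- as.matrix(stats::dist(X)) / sqrt(m)
  dimnames(d) <- NULL
  new("FrameDistanceMatrix", frameIndices = as.integer(frames), values = d)
}

## Deterministic relabelling: cluster 0 = most populated, ties broken by
## earliest member frame (mirrors the numbering of common MD tools, where
## cluster 0 is the dominant conformation).
relabelBySize <- function(raw) {
  tab <- table(raw)
  first <- vapply(names(tab), function(g) min(which(raw == g)), integer(1))
  ord <- order(-as.integer(tab), first)
  map <- stats::setNames(seq_along(ord) - 1L, names(tab)[ord])
  unname(map[as.character(raw)])
}

medoidOf <- function(d, members) {
  sums <- rowSums(d[members, members, drop = FALSE])
  members[which.min(sums)]  # lowest index on ties
}

#' Cluster-validity indices in medoid form
#'
#' For a metric with no coordinate mean, the classical sums of squares are
#' formed from distances to medoids: SSE is the summed squared
#' member-to-medoid distance, SST the summed squared distance to the global
#' medoid, SSR = SST - SSE (floored at 0). The pseudo-F statistic is
#' (SSR/(k-1)) / (SSE/(n-k)); the Davies-Bouldin index uses the mean
#' member-to-medoid distance as cluster spread and medoid-medoid distances
#' as separation.
#'
#' @param values symmetric distance matrix (or \code{FrameDistanceMatrix}).
#' @param labels integer cluster labels (any coding), one per row.
#' @return Named numeric: \code{dbi}, \code{psf}, \code{ssrSst}. A single
#'   cluster yields ssrSst 0 and NA for the others; SSE = 0 with k < n
#'   yields psf = Inf; SST = 0 flags all three as NA.
#' @export
validityIndices <- function(values, labels) {
  d <- if (is(values, "FrameDistanceMatrix")) values@values else
    as.matrix(values)
  n <- nrow(d)
  if (length(labels) != n) stop("one label per frame required")
  groups <- split(seq_len(n), labels)
  if (any(lengths(groups) == 0)) stop("every cluster must be non-empty")
  k <- length(groups)
  gmed <- medoidOf(d, seq_len(n))
  sst <- sum(d[, gmed]^2)
  if (sst <= 0)
    return(c(dbi = NA_real_, psf = NA_real_, ssrSst = NA_real_))
  if (k == 1)
    return(c(dbi = NA_real_, psf = NA_real_, ssrSst = 0))
  meds <- vapply(groups, function(ix) medoidOf(d, ix), integer(1))
  sse <- sum(vapply(seq_len(k), function(i)
    sum(d[groups[[i]], meds[i]]^2), numeric(1)))
  ssr <- max(sst - sse, 0)
  ssr_sst <- ssr / sst
  psf <- if (sse == 0 && k < n) Inf
         else if (k == n) NA_real_
         else (ssr / (k - 1)) / (sse / (n - k))
  spread <- vapply(seq_len(k), function(i)
    mean(d[groups[[i]], meds[i]]), numeric(1))
  dbi_terms <- vapply(seq_len(k), function(i) {
    ratios <- vapply(seq_len(k)[-i], function(j) {
      sep <- d[meds[i], meds[j]]
      if (sep == 0) return(if (spread[i] + spread[j] == 0) 0 else Inf)
      (spread[i] + spread[j]) / sep
    }, numeric(1))
    max(ratios)
  }, numeric(1))
  c(dbi = mean(dbi_terms), psf = psf, ssrSst = ssr_sst)
}

#' Cut an agglomerative clustering of trajectory frames at k clusters
#'
#' Average-linkage agglomeration (the package's fixed linkage for the
#' hierarchical clustering of frames) cut at \code{k}; deterministic given
#' the matrix. Clusters are renumbered so that cluster 0 is the most
#' populated. The medoid of a cluster is the member frame minimizing the
#' summed distance to the cluster's members.
#'
#' @param fdm a \code{FrameDistanceMatrix}.
#' @param k cluster count, 2 <= k <= n (k = n is permitted and degenerate).
#' @param hc optional precomputed \code{hclust} object (used by
#'   \code{\link{sweepK}} to avoid refitting).
#' @return A \code{ClusteringResult}.
#' @export
hierarchicalCluster <- function(fdm, k, hc = NULL) {
  stopifnot(is(fdm, "FrameDistanceMatrix"))
  n <- nrow(fdm@values)
  if (k < 1 || k > n) stop("k = ", k, " out of range [1, ", n, "]")
  if (is.null(hc))
    hc <- stats::hclust(stats::as.dist(fdm@values), method = "average")
  raw <- stats::cutree(hc, k = k)
  labels <- relabelBySize(raw)
  groups <- split(seq_len(n), factor(labels, levels = sort(unique(labels))))
  meds <- vapply(groups, function(ix) medoidOf(fdm@values, ix), integer(1))
  frac <- lengths(groups) / n
  idx <- validityIndices(fdm@values, labels)
  obj <- new("ClusteringResult", k = as.integer(k),
             labels = as.integer(labels),
             frameIndices = fdm@frameIndices,
             medoidFrame = as.integer(fdm@frameIndices[meds]),
             populationFraction = as.numeric(frac), indices = idx)
  validObject(obj)
  obj
}

#' Sweep the cluster count and pick k by a validity-index rule
#'
#' Clusters at every k in \code{[kMin, kMax]} (kMax is clipped to the frame
#' count) on one agglomerative tree. The default "psf-max" rule selects the
#' k maximizing the pseudo-F statistic, ties toward smaller k; "dbi-min"
#' minimizes the Davies-Bouldin index; "manual" returns \code{manualK}.
#'
#' @param fdm a \code{FrameDistanceMatrix}.
#' @param kMin,kMax sweep range (defaults 2 and 20).
#' @param rule "psf-max", "dbi-min" or "manual".
#' @param manualK the k to select under the "manual" rule.
#' @return A \code{KSweepReport}.
#' @export
sweepK <- function(fdm, kMin = 2L, kMax = 20L, rule = c("psf-max",
                   "dbi-min", "manual"), manualK = NULL) {
  rule <- match.arg(rule)
  stopifnot(is(fdm, "FrameDistanceMatrix"))
  n <- nrow(fdm@values)
  if (kMin < 2) stop("kMin must be >= 2")
  kMax <- min(kMax, n)
  if (kMin > kMax) stop("kMin exceeds the number of frames")
  hc <- stats::hclust(stats::as.dist(fdm@values), method = "average")
  ks <- seq(as.integer(kMin), as.integer(kMax))
  results <- lapply(ks, function(k) hierarchicalCluster(fdm, k, hc = hc))
  names(results) <- paste0("k", ks)
  sel <- switch(rule,
    "psf-max" = {
      psf <- vapply(results, function(r) r@indices["psf"], numeric(1))
      psf[is.na(psf)] <- -Inf
      ks[which.max(psf)]  # first max -> smaller k on ties
    },
    "dbi-min" = {
      dbi <- vapply(results, function(r) r@indices["dbi"], numeric(1))
      dbi[is.na(dbi)] <- Inf
      ks[which.min(dbi)]
    },
    "manual" = {
      if (is.null(manualK)) stop("manual rule requires manualK")
      if (manualK < kMin || manualK > kMax)
        stop("manualK outside the sweep range")
      as.integer(manualK)
    })
  new("KSweepReport", results = results, selectedK = as.integer(sel),
      selectionRule = rule)
}

#' Per-cluster descriptor summary
#'
#' For every cluster: population fraction, mean key-atom distance and mean
#' pocket volume over the cluster's (strided) member frames, the medoid's
#' side-chain RMSD to every reference exemplar, and the medoid's state
#' assignment.
#'
#' @param trajectory the clustered \code{CageTrajectory}.
#' @param result a \code{ClusteringResult}.
#' @param spec a \code{CageSpec}.
#' @param envelope optional \code{PocketEnvelope} (volumes NA without it).
#' @param library optional \code{ReferenceLibrary} (RMSD columns and
#'   assignment absent without it).
#' @param radii a \code{RadiiTable} for volume occupancy.
#' @return data.frame, one row per cluster (cluster, nFrames, fraction,
#'   meanKeyDistance, meanVolume, rmsd_<state>..., assignedState).
#' @export
clusterSummary <- function(trajectory, result, spec, envelope = NULL,
                           library = NULL, radii = defaultRadii()) {
  stopifnot(is(trajectory, "CageTrajectory"), is(result, "ClusteringResult"))
  sel <- resolveSelection(trajectory@topology, spec)
  frames <- result@frameIndices
  keyd <- vapply(frames, function(f)
    atomPairDistance(frameCoords(trajectory, f), sel@keyPairIdx), numeric(1))
  vols <- rep(NA_real_, length(frames))
  if (!is.null(envelope)) {
    vs <- volumeSeries(trajectory, envelope, radii = radii,
                       frames = frames)
    vols <- vs$volume
  }
  ks <- sort(unique(result@labels))
  rows <- lapply(ks, function(cl) {
    in_cl <- result@labels == cl
    med_frame <- result@medoidFrame[cl + 1L]
    row <- data.frame(cluster = cl, nFrames = sum(in_cl),
                      fraction = result@populationFraction[cl + 1L],
                      meanKeyDistance = mean(keyd[in_cl]),
                      meanVolume = mean(vols[in_cl]),
                      medoidFrame = med_frame)
    if (!is.null(library)) {
      med <- setCoords(trajectory@topology, frameCoords(trajectory,
                                                        med_frame))
      med@id <- paste0("frame", med_frame)
      asg <- classifyConformer(med, library)
      for (s in names(asg@rmsdToEach))
        row[[paste0("rmsd_", s)]] <- asg@rmsdToEach[[s]]
      row$assignedState <- asg@label
    }
    row
  })
  do.call(rbind, rows)
}

#' Serialize a k-sweep report to JSON
#'
#' @param report a \code{KSweepReport}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSweepReport <- function(report, path) {
  stopifnot(is(report, "KSweepReport"))
  per_k <- lapply(report@results, function(r)
    list(k = r@k,
         fractions = as.numeric(r@populationFraction),
         dbi = unname(r@indices["dbi"]), psf = unname(r@indices["psf"]),
         ssr_sst = unname(r@indices["ssrSst"])))
  jsonlite::write_json(list(selected_k = report@selectedK,
                            selection_rule = report@selectionRule,
                            per_k = per_k),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
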