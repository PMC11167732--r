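---
title: "Discriminating aromatic-cage states: methods and design choices"
author: "cageflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating aromatic-cage states: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the metric and
the statistics, every tunable parameter and why its default is what it is,
what the synthetic generator does and does not emulate, and the places
where the design was genuinely open and a choice had to be made.

## The problem

Aromatic cages — the Trp/Tyr/Phe pockets through which reader domains
such as Tudor modules recognize methylated lysines and arginines — adopt
discrete conformational states: closed (a flexible aromatic side chain
blocks access), one or more open states (that side chain flipped out,
pocket ligandable), sometimes a collapsed state (cage residues stacked
onto each other). Given (i) an ensemble of crystal structures and (ii) an
MD trajectory, the analysis must decide which states exist, which the
trajectory sampled, and with what populations.

## The metric

Every structural comparison in the package uses a single two-step
convention:

1. **Superpose on anchors only.** The mobile conformer is fitted onto the
   reference by a Kabsch (SVD) rigid fit over the cage residues' Cα
   atoms.
2. **Measure on side chains, no re-fit.** The RMSD is then taken over the
   cage residues' side-chain heavy atoms in the anchor-fitted frame.

This separates "where the cage sits" (absorbed by the anchor fit) from
"how the side chains are arranged" (the quantity of interest): a rigid
motion of a whole conformer contributes exactly zero, while a flipped
tryptophan contributes fully. Hydrogens are excluded everywhere, and
atoms are unweighted — mass weighting is a convention choice on which
reference implementations differ, so one convention is fixed and
documented. Atom correspondence is by (residue, atom name), with
selections resolved in a canonical (residue order, atom name) sort so
that permuting the residue list does not change the metric.

For trajectories, frames are prealigned **once** onto frame 1 (anchor
fit) and all pairwise side-chain RMSDs are computed in that common frame
without per-pair refitting. Per-pair refitting was the open alternative;
prealign-once is chosen because it makes the frame-frame distance a plain
Euclidean distance on fixed coordinate vectors (exactly computable with a
fast distance kernel, hence all-pairs matrices at thousands of frames),
and because with identical anchors the two conventions coincide up to the
anchor-noise scale, which is far below the 1.2 Å decision threshold.

## Reference libraries from crystal ensembles

The pairwise RMSD matrix of the ensemble is thresholded at *t* = 1.2 Å
and clustered by **single-linkage connected components**: structures are
in one cluster when a chain of below-threshold neighbours connects them.
Components of size one are reported as *singletons* — the "structure that
cannot be assigned to any cluster" case that real ensembles produce.
Connected components are the weakest assumption that reproduces
"clusters plus an unassignable entry", and they are deterministic and
order-free; a specific linkage dendrogram over an ensemble of a few
dozen structures would add assumptions without adding information.

Edges use **strict** inequality (RMSD < *t*), so a conformer at exactly
the threshold is *not* assigned; this makes exemplar self-assignment
(RMSD 0) and boundary cases unambiguous. The exemplar of a cluster is its
medoid (minimum summed RMSD to members) unless a curated pick overrides
it — the override path exists because practice curates references (an apo
structure for closed, an inhibitor-bound one for open) rather than taking
medoids.

Classification of any conformer computes its RMSD to every exemplar;
`label = argmin` if the minimum is below *t*, else `"novel"`; ties break
toward the earlier state in library order (deterministic).

## Trajectory clustering and the cluster count

Frames (optionally strided) are clustered by **average-linkage
hierarchical agglomeration** on the side-chain RMSD matrix. Average
linkage is the common default for trajectory RMSD clustering: single
linkage chains through transition frames, complete linkage shatters broad
basins; average linkage is the compromise. The linkage is a documented
choice, not a claim about what any particular reference workflow used.

The cut level is swept over k = 2…20 and scored by three indices
computed **in medoid form**, because the RMSD metric has no coordinate
mean: with d the metric, SSE = Σ_clusters Σ_members d(member, medoid)²,
SST = Σ_frames d(frame, global medoid)², SSR = max(SST − SSE, 0),

* SSR/SST — explained scatter, in [0, 1], non-decreasing in k;
* pSF = (SSR/(k−1)) / (SSE/(n−k)) — explained scatter per cluster spent;
* DBI = (1/k) Σ_i max_{j≠i} (s_i + s_j)/d(m_i, m_j), s the mean
  member-medoid distance.

On Euclidean point data with singleton-free clusters these reduce to the
classical definitions. Degenerate cases are flagged rather than fudged:
SSE = 0 with k < n reports pSF = +Inf; SST = 0 reports all three as NA;
k = 1 reports SSR/SST = 0.

The default selection rule is **psf-max** (ties toward smaller k).
Published workflows typically combine the indices with visual inspection
and state no formal rule; psf-max is this package's stated convention —
pSF is the only one of the three with a built-in parsimony trade-off —
and `dbi-min` and `manual` rules are selectable. Cluster ids are
renumbered so cluster 0 is the most populated (the numbering convention
of common MD tools), with ties broken by earliest frame; medoids break
ties by lowest frame index. Two runs on the same matrix are
byte-identical.

## Pocket volume

Volumes are counted on an **occupancy grid** inside a frozen envelope:

* The envelope is built from the open reference structures, superposed
  onto the first via cage anchors. The grid spans the bounding box of the
  cage side-chain atoms plus `pad` (default 5 Å) at `spacing` (default
  0.5 Å). A point is included when, in at least one open reference, it is
  within `pad` of a cage side-chain atom **and** unoccupied — farther
  than (vdW + probe) from every protein heavy atom (C 1.70, N 1.55,
  O 1.52, S 1.80, default 1.70; probe 1.4 Å). The union over references
  is taken, and the envelope is then frozen.
* Per frame, the conformation is anchor-fitted into the envelope frame
  and the unoccupied envelope points are counted; volume = count ×
  spacing³. This makes the per-frame volume anti-monotone in occupancy
  and bounded by the envelope volume by construction.

This deliberately replaces alpha-sphere pocket detection: an occupancy
grid is deterministic, dependency-free, and testable against analytic
cavities (a designed 3 Å spherical cavity of 113.1 Å³ is recovered to a
few percent at 0.5 Å spacing, and halving the spacing moves the estimate
by under 5%). The cost is that **absolute** volumes are not comparable
with alpha-sphere tools, whose published values depend on unstated
parameters; the package therefore treats reference volume values as
ordering/qualitative anchors (closed < open within a system), never as
bit-exact targets.

An important geometric consequence of the inclusion rule: it only yields
a bounded, pocket-shaped envelope when the protein body encloses the
pocket, because any unoccupied exterior point within `pad` of a
side-chain atom also qualifies. Real binding sites satisfy this; the
synthetic generator must, too — hence the scaffold shell below.

## Descriptor densities

Key atom-pair distances (rigid-invariant, measured on raw frames) and
per-frame volumes are summarized by Gaussian kernel densities with peak
detection (local maxima above 5% of the global maximum, on a grid
spanning the data ± 3 bandwidths). The default bandwidth is the
**geometric mean of the Sheather–Jones plug-in and Silverman
normal-reference bandwidths**. The reasoning, from a replicated
Monte-Carlo study of the estimator on mixture data of the kind the
pipeline produces (modes ≥ 2 Å apart, per-mode spread ≈ 0.28 Å from
σ = 0.2 Å coordinate noise, a few hundred observations per mode):
normal-reference rules use the full-mixture spread and oversmooth until
neighbouring modes merge (Scott ≈ 0.5 Å merges modes 2 Å apart), while
the plug-in alone (≈ 0.1 Å) leaves mode locations with a 90th-percentile
error above 0.1 Å at 200 observations per mode. Their geometric mean
(≈ 0.22 Å here) keeps ≥ 2 Å separations resolved with a 90th-percentile
mode error near 0.05 Å. All-identical inputs are degenerate-flagged, not
smoothed.

## The synthetic generator

`makeTemplate()` builds a toy cage whose ground truth is designable:

* 3+ pseudo-residues with idealized Trp/Tyr/Phe side-chain layouts
  (correct heavy-atom name sets, ~1.45 Å bond steps) on a fixed backbone;
  anchors are identical across states by construction.
* States differ by side-chain pose (tilt from the pocket-inward axis,
  twist about the residue axis, per-residue stagger): closed points
  inward and fills the pocket, the open states sweep along the pocket
  wall leaving it empty, collapsed fills it in a different arrangement.
* The cage sits inside a two-shell **scaffold** of atoms — a minimal
  protein body — so the pocket interior is the only unoccupied space
  within pad reach of the side chains and the envelope rule above yields
  a bounded pocket (see the geometric note in the volume section).
* Key atom-pair distances per state are calibrated exactly to designed
  values (default 6.0/9.5/8.9/4.0 Å for closed/open1/open2/collapsed,
  mirroring the distance contrast between crystallographic closed and
  open cage states) by placing the tip atom at the designed distance.
* Construction **verifies** its own invariants — pairwise inter-state
  side-chain RMSD ≥ 2 Å, closed-vs-open key-distance contrast ≥ 2.5 Å
  (relaxable for stand-ins emulating systems whose published contrast is
  smaller), closed pocket volume < 10% of every open state's — and fails
  after bounded retries rather than returning a template that violates
  them. The designed gaps stored in the template are recomputed with the
  package's own metric, never assumed.

`simulateTrajectory()` adds i.i.d. Gaussian coordinate noise (default
σ = 0.2 Å) and an optional random rigid motion per frame (on by default —
it is what the anchor superposition must remove), with instantaneous
segment transitions so labels are unambiguous; a linear-interpolation
mode exists for testing density bimodality under slow transitions.
`placeProbes()` and `probeCountForMolarity()` produce uniform
minimum-separation point sets and probe counts for a target molarity,
for radial-distribution-function checks (g(r) ≈ 1 in the bulk for a
homogeneous distribution).

What passing tests on this generator do show: the measurement chain —
parsing, selection, superposition, the RMSD metric, threshold and
agglomerative clustering, the validity indices, volume counting,
classification, reporting — is correct against closed forms, brute-force
oracles and designed ground truth. What they do not show: force-field or
solvent realism, gradual conformational transitions, correlated thermal
motion, crystallographic noise models, or which chemical probes open
which pocket. The generator's states move as rigid side-chain poses plus
isotropic noise; real side chains move through dihedral paths.

`syntheticReferenceEnsemble()` extends the generator to stand-in crystal
ensembles for two reader systems (a tandem-Tudor reader with two cages,
19 entries; a single-Tudor reader, 6 entries): residue rosters and key
atom pairs of the real systems, designed reference distances equal to
the published reference values, cluster composition (12 + 6 + 1
unassignable; 2 + 3 + 1) and volume orderings reproduced by
construction. All ids carry a `SYN-` prefix: these are generator
coordinates for exercising the machinery, not deposited structures, and
agreement with them validates the pipeline, not the crystallography.

## Parameters at a glance

| parameter | default | unit | rationale |
|---|---|---|---|
| assignment threshold *t* | 1.2 | Å | separates within-state noise (≲0.5 Å at σ = 0.2 Å) from inter-state gaps (≥ 2 Å) |
| anchor atoms | CA | — | backbone-invariant superposition |
| k sweep | 2–20 | — | brackets plausible state counts |
| selection rule | psf-max | — | parsimony-aware index; alternatives selectable |
| stride | 1 (10 recommended at 10⁴ frames) | frames | all-pairs RMSD is O(n²) |
| grid spacing | 0.5 | Å | <5% volume change on halving |
| probe radius | 1.4 | Å | water-sized probe |
| pad | 5.0 | Å | one hydration shell beyond the cage |
| noise σ (generator) | 0.2 | Å | thermal-scale jitter, small vs gaps |
| KDE bandwidth | hybrid (SJ×Silverman)^½ | data units | mode-location study above |

## Problem sizes

The test suite and the acceptance script run, per invocation: a
1,000-frame three-state trajectory at stride 1 (all-pairs distance
matrix, full k sweep), stand-in ensembles of 19 and 6 structures,
envelope grids of ~10⁵ candidate points, 10,000-point RDF checks, and
brute-force oracles on ≤ 8-point/frame instances — sizes chosen so every
stage, including its oracles, runs end to end in a few minutes on one
CPU while keeping each statistical check comfortably powered.

## Known limitations

* Absolute pocket volumes are method-specific (occupancy grid vs
  alpha-spheres); only orderings and ratios are portable.
* Threshold clustering of ensembles answers "which structures are the
  same state", not "how many states exist" — a singleton may be a state
  or an artifact; curation decides.
* The state verdict is medoid-based: a state sampled only transiently,
  never dominating a cluster, can be missed at coarse k; the per-frame
  classification path is available when that matters.
* Classification is RMSD-based; conformations that are functionally open
  but differ in a single side-chain orientation can exceed the threshold
  against every open reference (observed in practice), so descriptors
  (distance, volume) are reported alongside labels and overriding is
  left to the user.
* No mmCIF writing, no hydrogen placement, no structure preparation; DCD
  and XTC readers are not included — the multi-model PDB dialect is the
  trajectory interchange format.
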