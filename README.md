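# cageflex

Conformational state analysis of aromatic cages in reader domains.

Methyl-lysine and methyl-arginine reader modules such as Tudor domains
recognize their marks through an *aromatic cage*: a pocket of two to five
Trp/Tyr/Phe side chains that engages the methylated ammonium group via
cation–π and hydrophobic contacts. Crystal structures show that these cages
interconvert between **closed** conformations (a flexible aromatic side
chain blocks the pocket), one or more **open** conformations (the side
chain flips out, making the pocket ligandable), and occasionally a
**collapsed** conformation in which cage residues stack onto each other.
Whether a simulation — typically a cosolvent MD run with organic probe
molecules — samples the ligandable open states is the question this
package answers quantitatively.

`cageflex` is aimed at computational chemists who post-process structural
ensembles and MD trajectories. It provides, end to end:

* **Reference states from crystal ensembles.** Pairwise side-chain
  heavy-atom RMSD matrices over an ensemble, single-linkage threshold
  clustering at a cutoff *t* (default 1.2 Å), medoid or curated exemplars
  per cluster, singleton detection for unassignable structures.
* **Trajectory clustering.** Hierarchical agglomerative (average-linkage)
  clustering of frames with the side-chain RMSD metric, a cluster-count
  sweep (k = 2…20) scored by the Davies–Bouldin index, the pseudo-F
  statistic and the SSR/SST ratio, and medoid representative frames.
* **Descriptor tracking.** Key atom-pair distances and grid-based pocket
  volumes inside a fixed envelope derived from open reference structures,
  per frame, with kernel-density summaries and peak detection.
* **Classification.** Each conformer or cluster medoid is assigned to the
  closest reference state if its side-chain RMSD is below *t*, else
  labelled `novel`.
* **Synthetic ground truth.** A generator for toy cages with designable
  state geometry (exact key distances, RMSD gaps ≥ 2 Å, pockets that close
  and open), noisy multi-state trajectories with per-frame labels, and
  probe point sets — so every stage is testable without MD output.

## The metric and the statistics

All comparisons use one convention: structures (or frames) are superposed
on the **Cα anchor atoms of the cage residues only** (Kabsch fit), then
the RMSD is measured over the **side-chain heavy atoms** without
re-fitting:

```
RMSD(a, b) = sqrt( mean_i | x_i^a − R x_i^b − t |² ),   (R, t) = argmin over anchors
```

Cluster validity indices are computed in medoid form, well-defined for any
metric: SSE = Σ_clusters Σ_members d(member, medoid)², SST = Σ d(frame,
global medoid)², SSR = SST − SSE,

```
SSR/SST ∈ [0, 1],   pSF = (SSR/(k−1)) / (SSE/(n−k)),
DBI = (1/k) Σ_i max_{j≠i} (s_i + s_j) / d(m_i, m_j)
```

with s the mean member–medoid distance. Pocket volume is an occupancy
grid: a point of the frozen envelope (0.5 Å spacing) counts as open when
it is farther than vdW + probe radius (1.4 Å) from every protein heavy
atom.

## Worked example

```r
library(cageflex)

tmpl <- makeTemplate(seed = 7)
tmpl
#> CageTemplate 'syncage-seed7': states closed, open1, open2, collapsed
#>   key distances [A]: closed 6.00, open1 9.50, open2 8.90, collapsed 4.00

sim <- simulateTrajectory(tmpl, c(closed = 500, open1 = 300, collapsed = 200),
                          noiseSigma = 0.2, seed = 7)

spec <- tmpl@cageSpec
refs <- lapply(stateNames(tmpl), function(s) stateStructure(tmpl, s))
env  <- buildEnvelope(refs[grep("^open", stateNames(tmpl))], spec)
lib  <- libraryFromExemplars(refs, stateNames(tmpl), spec, envelope = env)

rep <- stateReport(sim$trajectory, spec, lib, envelope = env,
                   kMin = 2, kMax = 20, stride = 5)
rep$selectedK
#> [1] 3
rep$verdict
#> [1] "closed"    "open1"     "collapsed"
```

The per-cluster table mirrors the usual trajectory-clustering report —
population fraction, mean key distance (Å), mean pocket volume (Å³),
medoid RMSD (Å) to each reference, assigned state:

```
  fraction meanKeyDistance meanVolume rmsd_closed rmsd_open1     state
1      0.5           5.999      8.464       0.315      5.382    closed
2      0.3           9.484    309.425       5.385      0.315     open1
3      0.2           4.022     40.525       3.059      6.718 collapsed
```

The pipeline recovers the scheduled 0.5/0.3/0.2 populations exactly, the
closed cluster shows the short key distance and a near-zero pocket, the
open cluster a ~9.5 Å distance and a ~310 Å³ pocket, and each medoid sits
within 0.32 Å of its generating reference. The distance density peaks land
at 4.02/6.01/9.49 Å against designed values of 4.0/6.0/9.5 Å:

```r
round(rep$distanceDensity$peaks, 2)
#> [1] 4.02 6.01 9.49
```

`runPipeline("config.yaml")` wraps the same stages behind a YAML config
(see `?runPipeline`), and `inst/cli/cageflex.R` exposes `run` and `synth`
subcommands for shell use.

A note on reference data: the package ships **no crystal coordinates**.
`syntheticReferenceEnsemble()` generates stand-in ensembles (ids prefixed
`SYN-`) whose residue rosters, key atom pairs, designed reference
distances, cluster composition and volume orderings emulate the published
ensembles of the SPIN1 and SMN reader systems; they exercise the full
measurement machinery but are generator output, not deposited structures.
To analyze real systems, point the pipeline at local PDB files.

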