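---
title: "Methods: topological cluster analysis of SMLM point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topological cluster analysis of SMLM point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toposmlm)
```

This vignette documents the statistical model, the algorithms, the default
parameters (with units and rationale) and the design decisions behind
`toposmlm`. It is the reference for *why* the package behaves the way it
does; the function help pages describe *what* each function computes.

## 1. Data model

The unit of data is the **detection**: one localized blinking event, with a
fitted position in nanometres (2D or 3D), and optionally the camera frame,
the photon count of the fit and the **localization uncertainty** — the
estimated standard deviation of the position error, in nm. A molecule
typically contributes many detections (several fluorophore labels, several
blinks each), and a fraction of the table is false detections from
background. Detection tables are plain data frames (`detection_table()`)
and round-trip through ThunderSTORM-style delimited text
(`read_detections()` / `write_detections()`).

Two standard cleaning steps for real data are provided:

* `filter_by_intensity()` with a default of **1000 photons** (inclusive):
  dim fits carry large localization errors, and 1000 photons is a standard
  cutoff for the bright dSTORM dye/camera combinations this workflow targets.
* `link_consecutive_frames()` with a default radius of **75 nm**: a
  fluorophore that stays on across frames is localized once per frame;
  detections in strictly consecutive frames within 75 nm are greedily
  chained and merged (intensity-weighted mean position, summed intensity,
  first frame, minimum uncertainty). 75 nm is several localization SDs, so
  genuinely distinct molecules are rarely merged.

## 2. ToMATo clustering

`tomato_cluster()` implements persistence-guided mode seeking:

1. **Density estimate.** The fixed-radius graph `build_radius_graph()`
   connects detections within distance `r` (boundary inclusive). The density
   of a detection is its degree — the number of neighbours within `r`
   (`radius_count_density()`, unit: detections).
2. **Mode seeking.** Processing detections in decreasing density order, a
   detection with no strictly denser neighbour starts a candidate cluster
   (birth density `f_b`); otherwise it joins the candidate of its densest
   strictly-higher neighbour.
3. **Persistence merging.** When two candidates first touch at density level
   `f_d` (a saddle), the one with lower birth density dies there. If its
   prominence `f_b − f_d` is below the threshold `τ`, it is merged into the
   other; otherwise both continue.
4. **Noise rule.** After the sweep, a surviving candidate becomes a cluster
   only if its prominence reaches `τ`; candidates that never reach it — weak
   isolated density islands that cannot be linked to any persistent cluster —
   are labelled noise (label 0). Consequently `τ = 0` yields one cluster per
   density mode with no noise, and a `τ` above the maximal density labels
   everything noise: the scheme degenerates to a local density threshold as
   `τ` grows. The per-candidate (birth, death) pairs are returned as the
   ToMATo diagram (`tomato_diagram()`); the top candidate of each connected
   component never dies and is recorded with death `−∞`.

Since the radius-count density is integer valued, ties are common; the
implementation breaks all of them deterministically (towards lower detection
index), so results are reproducible and permutation-equivariant. The
reference parameter scan used for benchmarking is `r` from 1–50 nm crossed
with `τ` from 0–50 detections (`parameter_grid("tomato")`), which brackets
localization precision to cluster scale and all useful prominence levels for
cluster sizes up to a few hundred detections.

**Baselines** for benchmarking: `dbscan_cluster()` (classic DBSCAN; the core
test counts the point itself), `ripley_cluster()` (threshold on the local
Ripley score `L_i = sqrt(A·k_i / (π(n−1)))`, which has expectation ≈ `r`
under complete spatial randomness), and `voronoi_cluster()` (keep tiles
below a maximal area, grow clusters through tile adjacency). All share the
convention: integer labels, 0 = noise.

## 3. Persistent homology of clusters

`rips_persistence()` computes the persistence diagram of the Vietoris–Rips
filtration of one cluster's detections: a simplex enters at the scale equal
to its longest edge, so the scale axis is an edge length in nm. H0 tracks
connected components, H1 holes, and — for 3D data analysed with
`max_dim = 3` — H2 enclosed voids. Features alive at `max_scale` are
reported with death `∞`; zero-persistence pairs are dropped.

Numerical design: H0 is computed by union–find over the sorted edges;
H1/H2 by boundary-matrix reduction over GF(2) with the standard
twist/clearing optimization (higher-dimensional simplices are reduced first
so that their pivots clear positive columns below), an apparent-pairs fast
path, and dense bitset columns. Exact distances are used throughout — no
approximation of the filtration. The computation is exponential in ambient
simplex count, so it is guarded to per-cluster point sets (`n ≤ 2500`);
segment the field first. The test suite verifies the implementation against
a full, unoptimized boundary-matrix reduction written independently in R,
and against analytic values for regular polygons (for `m` points evenly
spaced on a circle of radius `R`, the hole is born at `2R·sin(π/m)` and dies
at `2R·sin(⌈m/3⌉π/m)`) and the octahedron's void.

The **topological configuration** of a cluster (`threshold_diagram()`)
counts features with persistence at or above a threshold, default
**15 nm** — comfortably above the spurious features generated by a median
localization SD of ≈ 16 nm (spurious pairs sit near the diagonal), while
genuine structures at the scale of tens of nm persist far longer.

### Sub-sampled consensus

A single diagram is sensitive to individual noise detections, which can
bridge a hole or punch an artificial one. `subsample_consensus()` therefore
resamples the cluster with replacement (sample size = cluster size),
collapses duplicates, and computes the thresholded configuration per
resample; `per_cluster_topology()` applies this to every cluster of a
segmentation. Resampling probabilities follow the localization uncertainty:
`p_i ∝ exp(−μ·w_i)` with `w_i` the min–max-normalized uncertainty within
the cluster. The default `μ = −ln 0.1 ≈ 2.3` makes the most precise
detection exactly 10× likelier than the least precise. The **consensus** is
the modal configuration over `n_resamples = 100` resamples (ties go to the
simplest configuration), and the **agreement `α`** is the percentage of
resamples producing it. The conventional ring filter
(`filter_clusters_by_topology()`) keeps clusters with consensus
`holes = 1` and `α > 90%` (strict).

## 4. The dSTORM simulator

`simulate_smlm()` separates molecule placement from photophysics.

Scenario layouts (`scenario_config()`): complete spatial randomness,
isotropic Gaussian clusters, Gaussian cluster *pairs* at a fixed centre
separation, and rings with molecules evenly spaced on the circumference.
Cluster centres go on a jittered grid with a margin so structures stay in
the field.

Photophysics (`photophysics_config()`), applied per molecule:

| parameter | default | unit | rationale |
|---|---|---|---|
| fluorophores/molecule | Poisson, mean 5 | – | typical antibody label stoichiometry |
| blinks/fluorophore | geometric on {1,2,…}, `p_dark = 0.5` → mean 2 | – | dSTORM on/off kinetics |
| blink detection rate | 0.70 | – | localization software miss rate |
| localization SD | log-normal, meanlog 2.8, sdlog 0.28 | nm | median `exp(2.8) ≈ 16.4` nm, right-skewed as observed for real fits; each detection's SD is also reported as its uncertainty |
| noise fraction | 0.10 of the final table | – | uniformly distributed false detections |

Each detected blink is displaced from its molecule by isotropic normal error
with its drawn SD. The number of false detections is
`round(nf/(1−nf) · n_true)`, so they make up the nominal fraction of the
final table. Ground truth (per-detection structure label and generating
molecule, plus event counts) is returned for benchmarking, and the empirical
rates of a large simulation match the nominal ones (this is asserted to
within 3 standard errors in the test suite).

Known realism limits: photon counts are not modelled (so simulated tables
have no `intensity` column), frames are drawn uniformly (no temporal
correlation of blinks — frame linking is a pre-processing step for real
data), and detector pixelation/drift are out of scope.

### Study conditions

Scenario geometry used by the packaged experiments (`scripts/acceptance.R`)
and the examples, chosen once as representative of dSTORM cluster biology
and desk-scale compute: Gaussian clusters with SD 10 nm and 30
molecules/cluster; rings of radius 60 nm with 16 molecules; fields of
≈ 2 µm with a 200 nm margin; ToMATo at `r` = 30 nm, `τ` = 20 for
segmenting well-separated structures; a filtration cap of 130 nm (just above
the ring diameter) for per-cluster homology. The separation benchmark scans
each algorithm over a fixed grid wide enough that every algorithm's optimum
is interior to its grid, evaluates mean percent-correct over 5 replicate
fields, and reports each algorithm at its own best parameters.

## 5. Benchmarking and statistics

* `percent_correct()` matches predicted to true clusters one-to-one,
  greedily by overlap (largest first, ties to lower labels), then classifies
  every detection as correct, false positive (true noise in a cluster),
  false negative (cluster member sent to noise) or misassigned. The test
  suite checks the greedy matching against exhaustive optimal matching on
  small fixtures.
* `cluster_stats()` reports per-cluster convex-hull area (2D) or volume
  (3D; exact incremental hull) and cluster density per µm².
* `radial_profile()` histograms centroid distances per cluster (5 nm bins
  by default), normalizes within each cluster so large clusters do not
  dominate, and averages; the peak bin centre estimates a ring radius. Bins
  follow R's `hist()` convention (right-closed).
* `benchmark_clustering()` evaluates algorithms over parameter grids on
  simulated replicate suites (`generate_benchmark_suite()`), reporting the
  full performance surface and each algorithm's maximum of the
  replicate-mean percent correct.

Determinism: all stochastic steps derive their seeds from a master seed via
`derive_seed()` (an iterated linear congruence), so pipelines
(`run_pipeline()`), suites and the acceptance script are pure functions of
their seed.

## 6. Design decisions and limitations

* **Noise semantics of ToMATo.** Merging alone never produces noise; the
  noise designation comes from the final prominence test (§2, step 4). The
  package deliberately treats "cannot be linked to any persistent cluster"
  as noise rather than keeping every component, because isolated sparse
  islands in SMLM data are nearly always background. The diagram still
  records every candidate, so no information is lost.
* **Voronoi functions are 2D.** The tessellation is computed by exact
  per-cell half-plane clipping, which is simple and robust in 2D; a 3D
  version would require a full 3D cell complex for little benefit, since the
  Voronoi baseline is conventionally applied to 2D data. Exactly coincident
  detections share their site's tile (each gets the full tile area and
  mutual adjacency); tiles of the open plane that are unbounded read as
  density 0 unless `clip = TRUE`.
* **Uncertainty interpretation.** The log-normal parameters are on the log
  scale (meanlog/sdlog). On the natural scale the same numbers would imply
  sub-nanometre localization, which no dSTORM instrument achieves.
* **Consensus duplicate handling.** With-replacement resamples contain
  duplicates, which are collapsed before the filtration — a Rips complex
  over duplicated points would report the duplicates as zero-persistence
  artifacts and change nothing else, but collapsing keeps the complexes
  small.
* **Per-cluster homology scope.** Homology is computed per segmented
  cluster, not on the full field: the quantity of interest is the shape of a
  cluster, and field-level diagrams are dominated by inter-cluster
  structure. Clusters below `min_size = 4` detections are skipped (a Rips
  H1 feature needs at least 4 points above the noise floor to be
  meaningful).
* **Exactness over speed.** Distances, hulls and tessellations are exact;
  the only approximations in the package are statistical (resampling), never
  numerical shortcuts. The persistence reduction is feasible to roughly
  2000 points per cluster at `max_dim = 2` on one CPU core.
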