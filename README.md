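# toposmlm

Topological data analysis for single-molecule localization microscopy
(SMLM/dSTORM) point clouds.

SMLM experiments produce a table of *detections* — fitted fluorophore blink
positions with nanometre precision — rather than an image. Because one
molecule blinks many times and localization errors of 10–20 nm blur every
position, classic density-based cluster analysis struggles exactly where the
biology gets interesting: closely spaced or partially overlapping protein
clusters, and cluster *shapes* (is it a solid patch or a ring?). This package
approaches both problems with tools from topological data analysis:

* **ToMATo clustering** — mode seeking on a local density estimate with
  persistence-based merging. Every local density maximum starts a candidate
  cluster with birth density `f_b`; when two candidates meet at a saddle of
  density `f_d`, the one with lower birth dies, and candidates with
  topographic persistence `P = f_b − f_d` below a threshold `τ` are merged.
  Survivors with `P ≥ τ` become clusters; everything that cannot be linked to
  a persistent cluster is noise. The persistence diagram of candidates makes
  choosing `τ` a visual task.
* **Persistent homology of clusters** — each segmented cluster's detections
  are fed through a Vietoris–Rips filtration: a simplex enters at the scale
  equal to its longest edge, and connected components (H0), holes (H1) and
  enclosed voids (H2, for 3D data) are tracked as (birth, death) scale pairs.
  Features with persistence `death − birth` above a threshold (15 nm by
  default, i.e. clearly above the localization error) define the cluster's
  *topological configuration*, e.g. "one hole" for a ring-like complex.
* **Sub-sampled consensus** — a single diagram is brittle against noise
  detections, so each cluster is resampled with replacement many times,
  weighting detection `i` by `exp(−μ·w_i)` with `w_i` its min–max-normalized
  localization uncertainty (`μ = −ln 0.1` makes the most precise detection
  10× likelier than the least precise). The modal configuration over
  resamples is the consensus, and the fraction of resamples that agree is the
  agreement score `α`. Filtering for, say, `holes = 1` with `α > 90%` picks
  out genuine ring structures.
* **Baselines and benchmarking** — DBSCAN, per-detection Ripley-`L`
  thresholding and Voronoi-tessellation clustering, parameter-grid scans, and
  segmentation scoring against simulated ground truth (percent correctly
  assigned detections, split into false positives, false negatives and
  misassignments).
* **A dSTORM simulator** — molecules placed by scenario (CSR, Gaussian
  clusters, cluster pairs at fixed separation, rings) and imaged with a
  calibrated photophysics model: Poisson(5) fluorophores per molecule,
  geometric blink counts (mean 2), 70% blink detection, log-normal
  localization SD (median ≈ 16.4 nm) and 10% uniformly distributed false
  detections, with full ground truth for benchmarking.
* **Pre-processing and I/O** — ThunderSTORM-style CSV import/export, photon
  count filtering, and merging of re-detections across consecutive frames.

## Worked example

Simulate four ring-shaped clusters (radius 60 nm) under the default
photophysics, segment with ToMATo, assign each cluster a consensus topology,
and average the radial profile of the clusters that look like rings:

```r
library(toposmlm)

sc  <- scenario_config("ring", field_size = c(2000, 2000), n_clusters = 4,
                       molecules_per_cluster = 16, ring_radius = 60,
                       margin = 300)
sim <- simulate_smlm(sc, photophysics_config(), seed = 42)
sim$detections
#> Detection table: 542 detections, 2D
#>   optional fields: frame, uncertainty

cl <- tomato_cluster(sim$detections, r = 30, tau = 20)
cl
#> SMLM clustering (tomato): 542 detections, 4 clusters, 58 noise
#>   parameters: r = 30, tau = 20, prefilter_quantile = NULL

set.seed(1)
topo <- per_cluster_topology(sim$detections, cl, pers_threshold = 15,
                             max_scale = 130)
topo
#> Per-cluster topology: 4 clusters analysed, 0 skipped (threshold 15 nm)
#>   label n_detections holes_full holes_consensus alpha
#> 1     1          133          1               1    88
#> 2     2          106          1               1    97
#> 3     3          136          1               1    89
#> 4     4          109          1               1    99

sel <- filter_clusters_by_topology(topo, want = c(holes = 1), min_alpha = 90)
sel
#> [1] 2 4

coords <- det_coords(sim$detections)
radial_profile(lapply(sel, function(L) coords[cl$labels == L, , drop = FALSE]))
#> Radial profile over 2 clusters: peak at 52.5 nm (bin width 5 nm)

percent_correct(sim$truth$labels, cl)
#> Assignment score: 98.52% correct of 542 detections
#>   errors: 2 false positive, 6 false negative, 0 misassigned
```

With only two clusters passing the strict filter the 5 nm peak bin still
wobbles around the true 60 nm radius; averaged over a few replicate fields
(tens of rings) it settles onto the bin containing 60 nm — that experiment is
part of `scripts/acceptance.R`.

Everything above is also available through a configuration-driven pipeline
(`pipeline_config()` → `run_pipeline()`, YAML round trip via
`write_pipeline_config()`), and through a thin command-line wrapper at
`inst/scripts/toposmlm` with `simulate`, `cluster`, `topology`, `stats`,
`radial`, `pipeline` and `fixtures` subcommands.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the model and its
assumptions, every default parameter with units and rationale, the numerical
design of the persistence computation, and known limitations. All exported
functions carry full help pages.
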