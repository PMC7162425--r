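#' Persistent homology of a Rips filtration
#'
#' Computes the persistence diagram of the Rips (Vietoris-Rips) filtration
#' of a point set. A simplex enters the filtration once all its vertices are
#' pairwise within the scale distance, so the scale parameter is an edge
#' length; the filtration is evaluated exactly over continuous scale up to
#' `max_scale`. Features are (dimension, birth scale, death scale) triples:
#' dimension 0 are connected components, dimension 1 holes (loops) and
#' dimension 2 enclosed voids (requires `max_dim = 3`, meaningful for 3D
#' data). Features still alive at `max_scale` are reported with death
#' `Inf`. Zero-persistence pairs are omitted.
#'
#' @param points a coordinate matrix (nm) or [detection_table()].
#' @param max_scale largest filtration scale in nm; defaults to the point
#'   set diameter, so a feature can only be reported as never-dying if it
#'   survives the complete filtration.
#' @param max_dim maximum simplex dimension: 2 (edges + triangles, gives H0
#'   and H1) or 3 (adds tetrahedra, gives H2).
#' @return An object of class `persistence_diagram`: a data.frame with
#'   columns `dimension`, `birth`, `death` and attributes `max_scale`,
#'   `max_dim`, `n_points`.
#' @examples
#' hexagon <- cbind(10 * cos(2 * pi * 0:5 / 6), 10 * sin(2 * pi * 0:5 / 6))
#' pd <- rips_persistence(hexagon)
#' pd[pd$dimension == 1, ]  # one hole: birth 10, death 10 * sqrt(3)
#' @export
rips_persistence <- function(points, max_scale = NULL, max_dim = 2) {
  coords <- if (is.matrix(points)) points else det_coords(points)
  if (!is.numeric(max_dim) || !(max_dim %in% 2:3))
    stop("unsupported max_dim (use 2 for H0/H1, 3 to add H2)")
  n <- nrow(coords)
  if (n < 1) stop("at least one point required")
  if (n > 2500)
    stop("rips_persistence is meant for per-cluster point sets (n <= 2500); ",
         "segment the data first")
  if (is.null(max_scale)) {
    max_scale <- if (n == 1) 1 else max(stats::dist(coords))
    if (max_scale <= 0) max_scale <- 1
  }
  if (max_scale <= 0) stop("max_scale must be > 0")
  m <- rips_persistence_cpp(as.matrix(coords), max_scale, as.integer(max_dim))
  pd <- as.data.frame(m)
  names(pd) <- c("dimension", "birth", "death")
  pd$dimension <- as.integer(pd$dimension)
  pd <- pd[order(pd$dimension, pd$birth, pd$death), , drop = FALSE]
  rownames(pd) <- NULL
  structure(pd, class = c("persistence_diagram", "data.frame"),
            max_scale = max_scale, max_dim = max_dim, n_points = n)
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("Persistence diagram: %d features (n = %d points, max scale %.3g)\n",
              nrow(x), attr(x, "n_points"), attr(x, "max_scale")))
  for (d in sort(unique(x$dimension)))
    cat(sprintf("  H%d: %d features\n", d, sum(x$dimension == d)))
  if (nrow(x)) print(as.data.frame(x))
  invisible(x)
}

#' @export
plot.persistence_diagram <- function(x, pers_threshold = NULL, ...) {
  fin <- is.finite(x$death)
  top <- max(c(x$death[fin], x$birth, attr(x, "max_scale")), na.rm = TRUE)
  death <- ifelse(fin, x$death, top * 1.05)
  cols <- c("black", "red", "blue")[x$dimension + 1]
  plot(x$birth, death, col = cols, pch = ifelse(fin, 16, 17),
       xlab = "birth scale [nm]", ylab = "death scale [nm]",
       xlim = c(0, top * 1.05), ylim = c(0, top * 1.05), ...)
  abline(0, 1, col = "grey50")
  if (!is.null(pers_threshold)) abline(pers_threshold, 1, lty = 2)
  legend("bottomright", pch = 16, col = c("black", "red", "blue")[1:3],
         legend = paste0("H", 0:2), bty = "n")
  invisible(x)
}

#' Bin a dense persistence diagram for heat-map display
#'
#' Groups diagram points into a joint histogram with square bins (1 nm by
#' 1 nm by default), as used when too many features overlap for a scatter
#' plot.
#'
#' @param pd a [rips_persistence()] diagram.
#' @param bin bin side length in nm.
#' @param dimension homology dimension to bin (default 1, holes).
#' @return data.frame of `birth`, `death` (bin centres) and `count`.
#' @export
bin_diagram <- function(pd, bin = 1, dimension = 1) {
  d <- pd[pd$dimension == dimension & is.finite(pd$death), , drop = FALSE]
  if (!nrow(d)) return(data.frame(birth = numeric(0), death = numeric(0),
                                  count = integer(0)))
  b <- floor(d$birth / bin) * bin + bin / 2
  dd <- floor(d$death / bin) * bin + bin / 2
  agg <- stats::aggregate(list(count = rep(1L, nrow(d))),
                          by = list(birth = b, death = dd), FUN = sum)
  agg
}

#' Topological configuration of a diagram
#'
#' Thresholds a persistence diagram by persistence (death minus birth) and
#' counts the surviving features per homology dimension >= 1: the number of
#' holes (H1) and, for 3D data analysed with `max_dim = 3`, voids (H2).
#' Never-dying features are counted as persistent. H0 is excluded (a
#' segmented cluster is a single component by construction) but reported in
#' the `n_components` attribute for diagnostics.
#'
#' @param pd a [rips_persistence()] diagram.
#' @param pers_threshold minimum persistence in nm (>= 0).
#' @return An integer vector of class `topo_configuration` with elements
#'   `holes` and (when the diagram was computed with `max_dim = 3`) `voids`.
#' @export
threshold_diagram <- function(pd, pers_threshold) {
  if (pers_threshold < 0) stop("pers_threshold must be >= 0")
  pers <- pd$death - pd$birth   # Inf for essential features
  keep <- pers >= pers_threshold
  holes <- sum(keep & pd$dimension == 1)
  cfg <- c(holes = holes)
  if (isTRUE(attr(pd, "max_dim") >= 3)) cfg <- c(cfg, voids = sum(keep & pd$dimension == 2))
  structure(as.integer(cfg), names = names(cfg), class = "topo_configuration",
            n_components = sum(keep & pd$dimension == 0))
}

#' @export
print.topo_configuration <- function(x, ...) {
  cat("Topological configuration:",
      paste(names(x), unclass(x), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

# canonical string key for tallying configurations
config_key <- function(cfg) paste(names(cfg), unclass(cfg), sep = "=", collapse = ",")

#' Uncertainty-weighted sampling probabilities
#'
#' Converts per-detection localization uncertainties into sub-sampling
#' weights `p = exp(-mu * w)`, where `w` is the uncertainty min-max
#' normalized to `[0, 1]` within the cluster. With the default
#' `mu = -log(0.1) = 2.3` the most precise detection in a cluster is ten
#' times more likely to be drawn than the least precise one. When all
#' uncertainties are equal (or absent) the weights are uniform.
#'
#' @param uncertainties numeric vector of localization uncertainties (nm).
#' @param mu weighting constant (>= 0).
#' @return Numeric sampling probabilities, normalized to sum to 1, with
#'   attribute `raw` (the unnormalized `exp(-mu * w)` weights).
#' @export
sampling_weights <- function(uncertainties, mu = -log(0.1)) {
  if (!length(uncertainties)) stop("at least one detection required")
  if (any(uncertainties < 0, na.rm = TRUE))
    stop("data error: negative localization uncertainty")
  if (mu < 0) stop("mu must be >= 0")
  rng <- range(uncertainties)
  w <- if (diff(rng) == 0) rep(0, length(uncertainties))
       else (uncertainties - rng[1]) / diff(rng)
  raw <- exp(-mu * w)
  structure(raw / sum(raw), raw = raw)
}

#' Sub-sampled consensus topology of a cluster
#'
#' The robust replacement for reading the topological configuration off a
#' single diagram: the cluster's detections are resampled with replacement
#' (sample size equal to the cluster size, probabilities from
#' [sampling_weights()] when uncertainties are given), duplicates are
#' collapsed, and the thresholded configuration is computed for every
#' resample. The modal configuration is returned as the consensus together
#' with the agreement `alpha`, the percentage of resamples that produced
#' it. Ties for the mode are broken towards the configuration with fewer
#' total features.
#'
#' @param points coordinate matrix of one cluster's detections (nm).
#' @param uncertainties optional localization uncertainties (nm).
#' @param pers_threshold persistence threshold in nm.
#' @param mu weighting constant (default `-log(0.1)`).
#' @param n_resamples number of with-replacement resamples (default 100).
#' @param max_dim maximum simplex dimension as in [rips_persistence()].
#' @param max_scale optional cap on the filtration scale (defaults to each
#'   resample's diameter).
#' @return An object of class `topo_consensus`: list with `consensus` (a
#'   `topo_configuration`), `alpha` (percent agreement), `n_resamples` and
#'   `table` (configuration frequencies).
#' @export
subsample_consensus <- function(points, uncertainties = NULL,
                                pers_threshold = 15, mu = -log(0.1),
                                n_resamples = 100, max_dim = 2,
                                max_scale = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 1, n_resamples >= 1)
  prob <- if (is.null(uncertainties)) rep(1 / n, n)
          else sampling_weights(uncertainties, mu)
  keys <- character(n_resamples)
  nfeat <- integer(0)
  cfgs <- list()
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(n, n, replace = TRUE, prob = prob)
    sub <- unique(points[idx, , drop = FALSE])
    cfg <- threshold_diagram(rips_persistence(sub, max_scale = max_scale,
                                              max_dim = max_dim),
                             pers_threshold)
    key <- config_key(cfg)
    keys[b] <- key
    if (is.null(cfgs[[key]])) {
      cfgs[[key]] <- cfg
      nfeat[key] <- sum(cfg)
    }
  }
  tab <- table(keys)
  best <- max(tab)
  cand <- names(tab)[tab == best]
  # modal configuration; ties -> simplest (fewest total features), then name
  cand <- cand[order(nfeat[cand], cand)]
  consensus <- cfgs[[cand[1]]]
  structure(list(consensus = consensus,
                 alpha = 100 * best / n_resamples,
                 n_resamples = n_resamples,
                 table = tab),
            class = "topo_consensus")
}

#' @export
print.topo_consensus <- function(x, ...) {
  cat(sprintf("Consensus configuration (%s) with agreement alpha = %.1f%% (%d resamples)\n",
              paste(names(x$consensus), unclass(x$consensus), sep = " = ",
                    collapse = ", "),
              x$alpha, x$n_resamples))
  invisible(x)
}

#' Per-cluster topology of a segmented detection table
#'
#' Runs persistent homology on every non-noise cluster of a clustering
#' result, returning both the configuration read from the full (all
#' detections) diagram and the sub-sampled consensus with its agreement.
#' Clusters below `min_size` detections are skipped (recorded with a
#' reason); the noise label 0 is never analysed.
#'
#' @param t a [detection_table()] (or coordinate matrix).
#' @param cr an `smlm_clustering` result for `t` (or a label vector).
#' @param pers_threshold persistence threshold in nm (default 15).
#' @param mu,n_resamples,max_dim,max_scale see [subsample_consensus()].
#' @param min_size smallest cluster analysed (default 4 detections).
#' @return A list of class `cluster_topology`: `table` (data.frame with one
#'   row per analysed cluster: label, n_detections, holes_full,
#'   holes_consensus, voids where applicable, and alpha), `consensus` (list
#'   of `topo_consensus` keyed by label), `diagrams` (full per-cluster
#'   diagrams) and `skipped` (labels with reasons).
#' @export
per_cluster_topology <- function(t, cr, pers_threshold = 15, mu = -log(0.1),
                                 n_resamples = 100, max_dim = 2,
                                 max_scale = NULL, min_size = 4) {
  labels <- if (inherits(cr, "smlm_clustering")) cr$labels else as.integer(cr)
  coords <- if (is.matrix(t)) t else det_coords(t)
  if (length(labels) != nrow(coords)) stop("labels must match detections")
  unc <- if (!is.matrix(t) && !is.null(t$uncertainty)) t$uncertainty else NULL
  labs <- sort(setdiff(unique(labels), 0L))
  rows <- list()
  consensus <- list()
  diagrams <- list()
  skipped <- list()
  for (L in labs) {
    ii <- which(labels == L)
    if (length(ii) < min_size) {
      skipped[[as.character(L)]] <- sprintf("cluster size %d below min_size %d",
                                            length(ii), min_size)
      next
    }
    pts <- coords[ii, , drop = FALSE]
    pd <- rips_persistence(pts, max_scale = max_scale, max_dim = max_dim)
    full <- threshold_diagram(pd, pers_threshold)
    cons <- subsample_consensus(pts, uncertainties = unc[ii],
                                pers_threshold = pers_threshold, mu = mu,
                                n_resamples = n_resamples, max_dim = max_dim,
                                max_scale = max_scale)
    row <- data.frame(label = L, n_detections = length(ii),
                      holes_full = full[["holes"]],
                      holes_consensus = cons$consensus[["holes"]],
                      alpha = cons$alpha)
    if (max_dim >= 3) {
      row$voids_full <- full[["voids"]]
      row$voids_consensus <- cons$consensus[["voids"]]
    }
    rows[[as.character(L)]] <- row
    consensus[[as.character(L)]] <- cons
    diagrams[[as.character(L)]] <- pd
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), n_detections = integer(0),
               holes_full = integer(0), holes_consensus = integer(0),
               alpha = numeric(0))
  rownames(tab) <- NULL
  structure(list(table = tab, consensus = consensus, diagrams = diagrams,
                 skipped = skipped,
                 parameters = list(pers_threshold = pers_threshold, mu = mu,
                                   n_resamples = n_resamples, max_dim = max_dim,
                                   max_scale = max_scale, min_size = min_size)),
            class = "cluster_topology")
}

#' @export
print.cluster_topology <- function(x, ...) {
  cat(sprintf("Per-cluster topology: %d clusters analysed, %d skipped (threshold %g nm)\n",
              nrow(x$table), length(x$skipped), x$parameters$pers_threshold))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}
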