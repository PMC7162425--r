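#' Per-cluster and per-field summary statistics
#'
#' For every non-noise cluster: detection count, centroid, and area (2D,
#' nm^2) or volume (3D, nm^3) of the convex hull of its member detections
#' (clusters with fewer than dim + 1 detections get measure 0). Field-level
#' summaries: mean cluster area and cluster density, the number of clusters
#' per square micrometre of field.
#'
#' @param t a [detection_table()] or coordinate matrix.
#' @param cr an `smlm_clustering` result or label vector (0 = noise).
#' @param field_area field area in nm^2 (2D) or volume in nm^3 (3D), used
#'   for the cluster density; e.g. `prod(field_size)`.
#' @return A list of class `cluster_stats`: `clusters` (data.frame: label,
#'   n_detections, area, centroid columns), `mean_area`, `n_clusters` and
#'   `cluster_density` (clusters per um^2 in 2D, per um^3 in 3D).
#' @export
cluster_stats <- function(t, cr, field_area) {
  if (missing(field_area) || !is.finite(field_area) || field_area <= 0)
    stop("field_area must be a positive number")
  labels <- if (inherits(cr, "smlm_clustering")) cr$labels else as.integer(cr)
  coords <- if (is.matrix(t)) t else det_coords(t)
  d <- ncol(coords)
  labs <- sort(setdiff(unique(labels), 0L))
  rows <- lapply(labs, function(L) {
    pts <- coords[labels == L, , drop = FALSE]
    cen <- colMeans(pts)
    area <- if (nrow(pts) < d + 1) 0 else hull_measure(pts)
    out <- data.frame(label = L, n_detections = nrow(pts), area = area)
    out[paste0("centroid_", c("x", "y", "z")[seq_len(d)])] <- as.list(cen)
    out
  })
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), n_detections = integer(0), area = numeric(0))
  um <- 1000^d   # nm^d per um^d
  structure(list(clusters = clusters,
                 n_clusters = length(labs),
                 mean_area = if (length(labs)) mean(clusters$area) else NA_real_,
                 cluster_density = length(labs) / field_area * um),
            class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf("Cluster statistics: %d clusters, mean area %.4g, density %.4g per um^dim\n",
              x$n_clusters, x$mean_area, x$cluster_density))
  invisible(x)
}

# convex hull area (2D) / volume (3D) of a point set
hull_measure <- function(pts) {
  if (ncol(pts) == 2) {
    h <- chull(pts)
    if (length(h) < 3) return(0)
    xs <- pts[h, 1]; ys <- pts[h, 2]
    abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  } else {
    hull_volume_cpp(as.matrix(pts))
  }
}

#' Averaged radial distribution of clusters
#'
#' For each cluster, the distances of its detections to the cluster centroid
#' (mean position) are histogrammed with bins of `bin_width`; counts are
#' normalized to frequencies within each cluster (so large clusters do not
#' dominate) and then averaged across clusters. The profile peak is the
#' centre of the maximal bin; for clusters with a ring topology it sits at
#' the ring radius.
#'
#' @param clusters a list of per-cluster coordinate matrices, or a single
#'   matrix.
#' @param bin_width histogram bin width in nm (> 0).
#' @param max_radius histogram range in nm; defaults to the largest
#'   centroid distance over all clusters, rounded up to a full bin.
#' @return A list of class `radial_profile`: `breaks`, `mid` (bin centres),
#'   `frequency` (averaged), `peak` (centre of maximal bin; ties -> smaller
#'   radius) and `n_clusters`.
#' @export
radial_profile <- function(clusters, bin_width = 5, max_radius = NULL) {
  if (bin_width <= 0) stop("bin width must be > 0")
  if (is.matrix(clusters)) clusters <- list(clusters)
  if (!length(clusters)) stop("at least one cluster required")
  radii <- lapply(clusters, function(p) {
    p <- as.matrix(p)
    cen <- colMeans(p)
    sqrt(colSums((base::t(p) - cen)^2))
  })
  if (is.null(max_radius)) max_radius <- max(unlist(radii), bin_width)
  breaks <- seq(0, ceiling(max_radius / bin_width) * bin_width, by = bin_width)
  freq <- vapply(radii, function(r) {
    h <- hist(pmin(r, max(breaks) - 1e-9), breaks = breaks, plot = FALSE)
    h$counts / max(1, length(r))
  }, numeric(length(breaks) - 1))
  if (is.null(dim(freq))) freq <- matrix(freq, ncol = length(radii))
  avg <- rowMeans(freq)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  structure(list(breaks = breaks, mid = mid, frequency = avg,
                 peak = mid[which.max(avg)], n_clusters = length(clusters)),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("Radial profile over %d clusters: peak at %g nm (bin width %g nm)\n",
              x$n_clusters, x$peak, diff(x$breaks[1:2])))
  invisible(x)
}

#' @export
plot.radial_profile <- function(x, ...) {
  plot(x$mid, x$frequency, type = "b", pch = 16,
       xlab = "distance from cluster centroid [nm]",
       ylab = "mean detection frequency", ...)
  abline(v = x$peak, lty = 2)
  invisible(x)
}

#' Select clusters by consensus topology
#'
#' Filters a [per_cluster_topology()] result to the cluster labels whose
#' consensus configuration equals `want` and whose agreement exceeds
#' `min_alpha` (strictly; the conventional filter is a single hole with
#' agreement > 90%).
#'
#' @param topo a `cluster_topology` result.
#' @param want target configuration: named integer vector (e.g.
#'   `c(holes = 1)`, plus `voids` for 3D analyses).
#' @param min_alpha agreement percentage that must be exceeded (default 90).
#' @return Integer vector of cluster labels.
#' @export
filter_clusters_by_topology <- function(topo, want = c(holes = 1), min_alpha = 90) {
  tab <- topo$table
  if (!nrow(tab)) return(integer(0))
  ok <- tab$alpha > min_alpha
  ok <- ok & tab$holes_consensus == want[["holes"]]
  if ("voids" %in% names(want)) {
    if (!"voids_consensus" %in% names(tab))
      stop("topology was computed without voids (max_dim = 2)")
    ok <- ok & tab$voids_consensus == want[["voids"]]
  } else if ("voids_consensus" %in% names(tab)) {
    ok <- ok & tab$voids_consensus == 0L
  }
  tab$label[ok]
}

#' Segmentation accuracy against ground truth
#'
#' Matches predicted clusters to ground-truth clusters one-to-one, greedily
#' by overlap size (largest overlap first; ties towards lower labels), then
#' scores each detection: correct when true noise is predicted noise or a
#' true cluster member is assigned to the cluster matched to its true
#' cluster. Errors are classified as false positives (true noise in a
#' predicted cluster), false negatives (true cluster member predicted
#' noise) and incorrect assignments (true cluster member in the wrong
#' predicted cluster).
#'
#' @param truth integer vector of true labels (0 = noise), or a simulator
#'   `truth` list.
#' @param cr an `smlm_clustering` result or predicted label vector.
#' @return A list of class `assignment_score`: `percent_correct`, counts
#'   `n_correct`, `false_positive`, `false_negative`,
#'   `incorrect_assignment`, `n`, and the `matching` (named integer vector,
#'   predicted label per true label, NA when unmatched).
#' @export
percent_correct <- function(truth, cr) {
  true <- if (is.list(truth) && !is.null(truth$labels)) truth$labels else truth
  pred <- if (inherits(cr, "smlm_clustering")) cr$labels else cr
  true <- as.integer(true); pred <- as.integer(pred)
  if (length(true) != length(pred)) stop("label vectors must have equal length")
  n <- length(true)
  tl <- sort(setdiff(unique(true), 0L))
  pl <- sort(setdiff(unique(pred), 0L))
  matching <- setNames(rep(NA_integer_, length(tl)), tl)
  if (length(tl) && length(pl)) {
    ov <- table(factor(true, levels = tl), factor(pred, levels = pl))
    ov <- matrix(ov, nrow = length(tl), dimnames = list(tl, pl))
    repeat {
      if (!any(ov > 0)) break
      best <- which(ov == max(ov), arr.ind = TRUE)
      # ties: lower true label, then lower predicted label
      best <- best[order(as.integer(rownames(ov)[best[, 1]]),
                         as.integer(colnames(ov)[best[, 2]])), , drop = FALSE]
      i <- best[1, 1]; j <- best[1, 2]
      matching[rownames(ov)[i]] <- as.integer(colnames(ov)[j])
      ov <- ov[-i, -j, drop = FALSE]
      if (!nrow(ov) || !ncol(ov)) break
    }
  }
  pred_of_true <- matching[as.character(true)]   # NA for true noise
  correct <- (true == 0L & pred == 0L) |
             (true != 0L & !is.na(pred_of_true) & pred == pred_of_true)
  fp <- true == 0L & pred != 0L
  fn <- true != 0L & pred == 0L
  mis <- true != 0L & pred != 0L & !correct
  structure(list(percent_correct = 100 * sum(correct) / n,
                 n_correct = sum(correct),
                 false_positive = sum(fp),
                 false_negative = sum(fn),
                 incorrect_assignment = sum(mis),
                 n = n, matching = matching),
            class = "assignment_score")
}

#' @export
print.assignment_score <- function(x, ...) {
  cat(sprintf("Assignment score: %.2f%% correct of %d detections\n",
              x$percent_correct, x$n))
  cat(sprintf("  errors: %d false positive, %d false negative, %d misassigned\n",
              x$false_positive, x$false_negative, x$incorrect_assignment))
  invisible(x)
}

#' Benchmark clustering algorithms on a simulated suite
#'
#' Evaluates each algorithm over its parameter grid on every dataset of a
#' [generate_benchmark_suite()] result: for each scenario, algorithm and
#' parameter set the percent of correctly assigned detections is averaged
#' across replicates; the reported performance of an algorithm on a
#' scenario is the maximum of this mean over its parameter grid. The full
#' performance surface per algorithm is also returned.
#'
#' @param suite a [generate_benchmark_suite()] result.
#' @param grids named list of [parameter_grid()] data.frames; names are the
#'   algorithm tags.
#' @return A list of class `benchmark_result`: `best` (data.frame:
#'   scenario, algorithm, percent_correct, best-parameter columns) and
#'   `surface` (data.frame with one row per scenario x algorithm x
#'   parameter set: mean percent correct across replicates).
#' @export
benchmark_clustering <- function(suite, grids) {
  man <- suite$manifest
  scen <- unique(man$scenario)
  surface <- NULL
  for (sname in scen) {
    reps <- man$rep[man$scenario == sname]
    # per replicate: cache radius graphs across parameter sets
    for (alg in names(grids)) {
      grid <- grids[[alg]]
      perf <- matrix(NA_real_, nrow(grid), length(reps))
      for (ri in seq_along(reps)) {
        key <- sprintf("%s_rep%d", sname, reps[ri])
        ds <- suite$datasets[[key]]
        coords <- det_coords(ds$detections)
        radius_col <- intersect(c("r", "eps"), names(grid))
        graphs <- list()
        if (length(radius_col)) {
          for (rv in unique(grid[[radius_col]]))
            graphs[[as.character(rv)]] <- build_radius_graph(coords, rv)
        }
        for (gi in seq_len(nrow(grid))) {
          g <- if (length(radius_col))
            graphs[[as.character(grid[[radius_col]][gi])]] else NULL
          cl <- run_clustering(coords, alg, grid[gi, , drop = FALSE], graph = g)
          perf[gi, ri] <- percent_correct(ds$truth$labels, cl)$percent_correct
        }
      }
      sf <- cbind(data.frame(scenario = sname, algorithm = alg), grid,
                  data.frame(mean_percent_correct = rowMeans(perf)))
      surface <- rbind_fill(surface, sf)
    }
  }
  best <- do.call(rbind, lapply(split(surface, list(surface$scenario, surface$algorithm),
                                      drop = TRUE), function(s) {
    i <- which.max(s$mean_percent_correct)
    out <- s[i, , drop = FALSE]
    names(out)[names(out) == "mean_percent_correct"] <- "percent_correct"
    out
  }))
  rownames(best) <- NULL
  structure(list(best = best, surface = surface), class = "benchmark_result")
}

# rbind data frames with different columns, padding with NA
rbind_fill <- function(a, b) {
  if (is.null(a)) return(b)
  for (cn in setdiff(names(b), names(a))) a[[cn]] <- NA
  for (cn in setdiff(names(a), names(b))) b[[cn]] <- NA
  rbind(a, b[names(a)])
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("Benchmark (max over parameter grid of mean percent correct):\n")
  print(x$best)
  invisible(x)
}
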