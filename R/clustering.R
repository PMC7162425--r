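#' Clustering results
#'
#' All clustering functions return an `smlm_clustering` object holding one
#' integer label per detection (0 = noise, 1..K = clusters), the algorithm
#' name and parameters, and — for ToMATo — the diagram of candidate clusters
#' (birth and death densities).
#'
#' @param labels integer vector of per-detection labels (0 = noise).
#' @param algorithm character tag.
#' @param parameters named list of parameters used.
#' @param diagram optional candidate-cluster diagram (see [tomato_cluster()]).
#' @return An object of class `smlm_clustering`.
#' @keywords internal
new_smlm_clustering <- function(labels, algorithm, parameters, diagram = NULL) {
  labels <- as.integer(labels)
  structure(list(labels = labels, algorithm = algorithm,
                 parameters = parameters, diagram = diagram,
                 n_clusters = length(setdiff(unique(labels), 0L))),
            class = "smlm_clustering")
}

#' @export
print.smlm_clustering <- function(x, ...) {
  cat(sprintf("SMLM clustering (%s): %d detections, %d clusters, %d noise\n",
              x$algorithm, length(x$labels), x$n_clusters, sum(x$labels == 0)))
  pars <- vapply(x$parameters, function(p) format(p), character(1))
  cat("  parameters:", paste(names(pars), pars, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.smlm_clustering <- function(object, ...) {
  sizes <- table(object$labels[object$labels > 0])
  cat(sprintf("%s clustering: %d clusters from %d detections (%.1f%% noise)\n",
              object$algorithm, object$n_clusters, length(object$labels),
              100 * mean(object$labels == 0)))
  if (length(sizes))
    cat(sprintf("  cluster sizes: min %d, median %g, max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  invisible(object)
}

#' @export
plot.smlm_clustering <- function(x, t, pch = 16, cex = 0.4, ...) {
  coords <- if (is.matrix(t)) t else det_coords(t)
  cols <- rep("black", length(x$labels))
  if (x$n_clusters > 0) {
    pal <- hcl.colors(max(3, x$n_clusters), "Dark 3")
    cols[x$labels > 0] <- pal[(x$labels[x$labels > 0] - 1) %% length(pal) + 1]
  }
  plot(coords[, 1], coords[, 2], col = cols, pch = pch, cex = cex, asp = 1,
       xlab = "x [nm]", ylab = "y [nm]", ...)
  invisible(x)
}

#' ToMATo persistence-based clustering
#'
#' Clusters detections by mode seeking on the radius-count density estimate
#' over the fixed-radius graph, then merges density modes by topographic
#' persistence. Every local density maximum starts a candidate cluster; its
#' birth density `f_b` is the density at the mode, and its death density
#' `f_d` is the saddle level at which it first meets a candidate of higher
#' birth density. Candidates whose persistence `P = f_b - f_d` is below the
#' threshold `tau` are merged into the stronger candidate they meet;
#' candidates that survive with `P >= tau` become the final clusters.
#' Detections whose surviving candidate never reaches persistence `tau`
#' (weak isolated density components, i.e. those that cannot be linked to
#' any persistent cluster) are labelled noise (0), which makes the scheme
#' behave like a local threshold on the density estimate.
#'
#' Determinism with the integer-valued radius-count density: a detection is
#' a mode iff no neighbour has strictly higher density; gradient and saddle
#' ties are broken towards lower detection indices.
#'
#' @param t a [detection_table()] or coordinate matrix.
#' @param r search radius in nm for both the density estimate and the graph.
#' @param tau persistence threshold in detections (>= 0).
#' @param graph,f optional precomputed radius graph and density (must match
#'   `r`).
#' @param prefilter_quantile optional density pre-filter: detections with
#'   density below this quantile are dropped to noise before clustering
#'   (recommended when the signal-to-noise ratio varies strongly).
#' @return An [new_smlm_clustering()] object; `$diagram` is a data.frame
#'   with one row per candidate cluster: `mode` (detection index), `birth`,
#'   `death` (`-Inf` for the highest peak of each graph component),
#'   `merged`, and `cluster` (final label containing the candidate).
#' @references The mode-seeking/persistence scheme follows Chazal, Guibas,
#'   Oudot and Skraba's Topological Mode Analysis Tool.
#' @examples
#' set.seed(1)
#' pts <- rbind(matrix(rnorm(100, 0, 5), 50), matrix(rnorm(100, 40, 5), 50))
#' cl <- tomato_cluster(pts, r = 10, tau = 5)
#' cl$n_clusters
#' @export
tomato_cluster <- function(t, r, tau, graph = NULL, f = NULL,
                           prefilter_quantile = NULL) {
  if (r <= 0) stop("parameter error: search radius must be > 0")
  if (tau < 0) stop("parameter error: tau must be >= 0")
  coords <- if (is.matrix(t)) t else det_coords(t)
  if (is.null(graph)) graph <- build_radius_graph(coords, r)
  if (is.null(f)) f <- radius_count_density(coords, r, graph = graph)

  keep <- seq_len(graph$n)
  nb <- graph$neighbors
  if (!is.null(prefilter_quantile)) {
    cut <- quantile(f, prefilter_quantile)
    keep <- which(f >= cut)
    remap <- integer(graph$n)
    remap[keep] <- seq_along(keep)
    nb <- lapply(nb[keep], function(v) {
      v <- remap[v]
      v[v > 0]
    })
    f_use <- f[keep]
  } else f_use <- f

  res <- tomato_cpp(nb, as.numeric(f_use), tau)
  labels <- integer(graph$n)
  labels[keep] <- res$labels
  diagram <- data.frame(mode = keep[res$mode], birth = res$diagram[, 1],
                        death = res$diagram[, 2],
                        merged = res$diagram[, 3] == 1,
                        cluster = res$cand_label)
  new_smlm_clustering(labels, "tomato",
                      list(r = r, tau = tau,
                           prefilter_quantile = prefilter_quantile),
                      diagram = diagram)
}

#' Extract and plot the ToMATo diagram
#'
#' Returns the (birth density, death density) pairs of all candidate
#' clusters, including the component roots at death `-Inf`; the persistence
#' of a candidate is its vertical distance from the diagonal. Because the
#' radius-count density is integer valued, many candidates can coincide;
#' `binned = TRUE` returns counts per unit (1 detection x 1 detection) cell
#' for heat-map display.
#'
#' @param cr an [tomato_cluster()] result.
#' @param binned if `TRUE` return a count per integer (birth, death) cell.
#' @return A data.frame of `birth`, `death` (and `count` when binned).
#' @export
tomato_diagram <- function(cr, binned = FALSE) {
  if (is.null(cr$diagram)) stop("clustering result carries no ToMATo diagram")
  d <- cr$diagram[, c("birth", "death")]
  if (!binned) return(d)
  agg <- stats::aggregate(list(count = rep(1, nrow(d))),
                          by = list(birth = round(d$birth), death = round(d$death)),
                          FUN = sum)
  agg
}

#' @rdname tomato_diagram
#' @param x an `smlm_clustering` object from [tomato_cluster()].
#' @param tau optional persistence threshold to draw as a dashed line.
#' @param finite_floor where to draw the `-Inf` death values.
#' @param ... passed to [plot()].
#' @export
plot_tomato_diagram <- function(x, tau = x$parameters$tau, finite_floor = NULL, ...) {
  d <- tomato_diagram(x)
  if (is.null(finite_floor))
    finite_floor <- min(c(d$death[is.finite(d$death)], 0)) - 0.1 * max(d$birth, 1)
  death <- ifelse(is.finite(d$death), d$death, finite_floor)
  plot(d$birth, death, xlab = "birth density [detections]",
       ylab = "death density [detections]", pch = 16, ...)
  abline(0, 1, col = "grey50")
  if (!is.null(tau)) abline(-tau, 1, lty = 2)
  invisible(x)
}

#' DBSCAN clustering
#'
#' Standard density-based spatial clustering: a detection is a core point
#' when at least `min_pts` detections (counting itself) lie within `eps`;
#' clusters are grown through core points, border points join the first
#' cluster that reaches them, everything else is noise.
#'
#' @param t a [detection_table()] or coordinate matrix.
#' @param eps neighbourhood radius in nm (> 0).
#' @param min_pts minimum neighbourhood size including the point itself
#'   (>= 1).
#' @param graph optional precomputed [build_radius_graph()] at radius `eps`.
#' @return An `smlm_clustering` object.
#' @export
dbscan_cluster <- function(t, eps, min_pts, graph = NULL) {
  if (eps <= 0) stop("parameter error: eps must be > 0")
  if (min_pts < 1) stop("parameter error: min_pts must be >= 1")
  if (is.null(graph)) graph <- build_radius_graph(t, eps)
  labels <- dbscan_cpp(graph$neighbors, as.integer(min_pts))
  new_smlm_clustering(labels, "dbscan", list(eps = eps, min_pts = min_pts))
}

#' Ripley's K-based clustering
#'
#' Thresholds the per-detection Ripley score ([ripley_local_score()]) and
#' forms clusters as connected components of the fixed-radius graph
#' restricted to the detections that pass the threshold; the rest is noise.
#'
#' @param t a [detection_table()] or coordinate matrix.
#' @param r search radius in nm.
#' @param score_threshold minimum Ripley score (same units as `r`).
#' @param window_area observation window area (see [ripley_local_score()]).
#' @param graph optional precomputed radius graph at radius `r`.
#' @return An `smlm_clustering` object.
#' @export
ripley_cluster <- function(t, r, score_threshold, window_area = NULL,
                           graph = NULL) {
  if (r <= 0) stop("parameter error: search radius must be > 0")
  if (is.null(graph)) graph <- build_radius_graph(t, r)
  sc <- ripley_local_score(t, r, window_area = window_area, graph = graph)
  keep <- sc >= score_threshold
  labels <- components_of_subset(graph$neighbors, keep)
  new_smlm_clustering(labels, "ripley",
                      list(r = r, score_threshold = score_threshold))
}

#' Voronoi tessellation clustering (2D)
#'
#' Keeps detections whose Voronoi tile area is at most `max_tile_area`
#' (unbounded/boundary tiles never qualify) and forms clusters as connected
#' components of the kept tiles under tile adjacency; the rest is noise.
#'
#' @param t a [detection_table()] or 2-column coordinate matrix.
#' @param max_tile_area largest tile area (nm^2) still considered clustered.
#' @param bbox,clip passed to [voronoi_density()].
#' @return An `smlm_clustering` object.
#' @export
voronoi_cluster <- function(t, max_tile_area, bbox = NULL, clip = FALSE) {
  f <- voronoi_density(t, bbox = bbox, clip = clip)
  area <- attr(f, "area")
  bnd <- attr(f, "boundary")
  keep <- (area <= max_tile_area) & (clip | !bnd)
  labels <- components_of_subset(attr(f, "adjacency"), keep)
  new_smlm_clustering(labels, "voronoi", list(max_tile_area = max_tile_area))
}

# connected components of the subgraph induced by `keep`; labels numbered by
# first (lowest-index) member, non-kept vertices 0
components_of_subset <- function(nb, keep) {
  n <- length(nb)
  labels <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (!keep[i] || labels[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    labels[i] <- nxt
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (j in nb[[v]]) {
        if (keep[j] && labels[j] == 0L) {
          labels[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Parameter grids for benchmarking
#'
#' Builds the deterministic Cartesian grid of parameter sets scanned when
#' benchmarking an algorithm (the reference scan for ToMATo is search radii
#' of 1 to 50 nm by 1 nm crossed with persistence thresholds of 0 to 50
#' detections by 1).
#'
#' @param algorithm one of `"tomato"`, `"dbscan"`, `"ripley"`, `"voronoi"`.
#' @param ... named numeric vectors of parameter values, e.g.
#'   `r = 1:50, tau = 0:50` for ToMATo. Names must match the clustering
#'   function's parameters.
#' @return A data.frame with one row per parameter set, in a stable
#'   row-major order, with attribute `algorithm`.
#' @export
parameter_grid <- function(algorithm = c("tomato", "dbscan", "ripley", "voronoi"),
                           ...) {
  algorithm <- match.arg(algorithm)
  vals <- list(...)
  expected <- switch(algorithm,
                     tomato = c("r", "tau"),
                     dbscan = c("eps", "min_pts"),
                     ripley = c("r", "score_threshold"),
                     voronoi = "max_tile_area")
  if (!length(vals)) {
    vals <- switch(algorithm,
                   tomato = list(r = 1:50, tau = 0:50),
                   stop("parameter values required for ", algorithm))
  }
  if (!setequal(names(vals), expected))
    stop("parameters for ", algorithm, " must be exactly: ",
         paste(expected, collapse = ", "))
  if (any(lengths(vals) == 0)) stop("empty parameter range")
  grid <- expand.grid(vals[expected], KEEP.OUT.ATTRS = FALSE)
  attr(grid, "algorithm") <- algorithm
  grid
}

#' Run one clustering algorithm with one parameter set
#'
#' Dispatch helper used by [benchmark_clustering()] and the pipeline: calls
#' the clustering function named by `algorithm` with the parameters in
#' `params` (a one-row data.frame or named list).
#'
#' @param t detection table or coordinate matrix.
#' @param algorithm algorithm tag as in [parameter_grid()].
#' @param params named list / one-row data.frame of parameters.
#' @param graph optional precomputed radius graph matching the radius-type
#'   parameter.
#' @return An `smlm_clustering` object.
#' @export
run_clustering <- function(t, algorithm, params, graph = NULL) {
  p <- as.list(params)
  switch(algorithm,
         tomato = tomato_cluster(t, r = p$r, tau = p$tau, graph = graph),
         dbscan = dbscan_cluster(t, eps = p$eps, min_pts = p$min_pts, graph = graph),
         ripley = ripley_cluster(t, r = p$r, score_threshold = p$score_threshold,
                                 graph = graph),
         voronoi = voronoi_cluster(t, max_tile_area = p$max_tile_area),
         stop("unknown algorithm: ", algorithm))
}
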