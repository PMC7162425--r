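#' Fixed-radius neighbour graph
#'
#' Builds the exact graph linking all detections within distance `r` of one
#' another (boundary inclusive: an edge is present iff the pairwise distance
#' is `<= r`). This is the Rips graph used both for the density estimate and
#' for mode seeking in ToMATo. A uniform-grid spatial index is used
#' internally; the result equals the brute-force O(n^2) graph.
#'
#' @param t a [detection_table()] or a coordinate matrix (nm).
#' @param r search radius in nm (> 0).
#' @return An object of class `radius_graph`: list with `n`, `r`,
#'   `neighbors` (per-detection sorted integer neighbour lists) and
#'   `edges` (two-column matrix, each undirected edge once with i < j).
#' @export
build_radius_graph <- function(t, r) {
  if (r <= 0) stop("parameter error: search radius must be > 0")
  coords <- if (is.matrix(t)) t else det_coords(t)
  nb <- radius_neighbors_cpp(coords, r)
  deg <- lengths(nb)
  from <- rep.int(seq_along(nb), deg)
  to <- unlist(nb, use.names = FALSE)
  keep <- from < to
  edges <- cbind(i = from[keep], j = to[keep])
  structure(list(n = nrow(coords), r = r, neighbors = nb, edges = edges),
            class = "radius_graph")
}

#' @export
print.radius_graph <- function(x, ...) {
  cat(sprintf("Fixed-radius graph: %d vertices, %d edges, r = %g nm\n",
              x$n, nrow(x$edges), x$r))
  invisible(x)
}

#' Radius-count density estimate
#'
#' The local detection density used by ToMATo: for every detection, the
#' number of other detections within distance `r` (the degree in the
#' fixed-radius graph; the detection itself is not counted).
#'
#' @param t a [detection_table()] or coordinate matrix.
#' @param r search radius in nm (> 0).
#' @param graph optionally a precomputed [build_radius_graph()] result for
#'   the same detections and radius.
#' @return Numeric vector of per-detection densities (unit: detections),
#'   with attributes `method = "radius_count"` and `r`.
#' @export
radius_count_density <- function(t, r, graph = NULL) {
  if (is.null(graph)) graph <- build_radius_graph(t, r)
  f <- as.numeric(lengths(graph$neighbors))
  attr(f, "method") <- "radius_count"
  attr(f, "r") <- graph$r
  f
}

#' Per-detection Ripley-type density score
#'
#' A local version of Ripley's L-function: with `k_i` neighbours within `r`
#' and observation-window area `A` (2D), `L_i = sqrt(A * k_i / (pi * (n - 1)))`.
#' Under complete spatial randomness `L_i` has expectation approximately `r`,
#' so clustering shows up as `L_i` above `r`. For 3D data the analogous form
#' with the window volume, `L_i = (3 * A * k_i / (4 * pi * (n - 1)))^(1/3)`,
#' is used.
#'
#' @param t a [detection_table()] or coordinate matrix.
#' @param r search radius in nm (> 0).
#' @param window_area observation window area in nm^2 (volume in nm^3 for
#'   3D); defaults to the bounding-box measure of the data.
#' @param graph optional precomputed radius graph.
#' @return Numeric score vector with attributes `method = "ripley"`, `r`.
#' @export
ripley_local_score <- function(t, r, window_area = NULL, graph = NULL) {
  coords <- if (is.matrix(t)) t else det_coords(t)
  n <- nrow(coords)
  if (is.null(window_area)) {
    span <- apply(coords, 2, function(v) diff(range(v)))
    window_area <- prod(span)
  }
  if (!is.finite(window_area) || window_area <= 0)
    stop("observation window area must be > 0")
  if (is.null(graph)) graph <- build_radius_graph(coords, r)
  k <- lengths(graph$neighbors)
  d <- ncol(coords)
  f <- if (d == 2) sqrt(window_area * k / (pi * (n - 1)))
       else (3 * window_area * k / (4 * pi * (n - 1)))^(1 / 3)
  attr(f, "method") <- "ripley"
  attr(f, "r") <- r
  f
}

#' Voronoi tessellation density estimate (2D)
#'
#' Computes the Voronoi tessellation of the detections and estimates the
#' local density of detection `i` as the reciprocal tile area,
#' `f_i = 1 / area_i`. Tiles of the open-plane tessellation that are
#' unbounded (equivalently: tiles touching the bounding box used for
#' clipping) are given density 0 by default, so detections on the field edge
#' read as low density; set `clip = TRUE` to use the box-clipped tile area
#' instead. Tile adjacency (shared tile edges, i.e. Delaunay neighbours) is
#' returned for cluster growth.
#'
#' @param t a [detection_table()] or 2-column coordinate matrix. 3D input is
#'   not supported.
#' @param bbox clipping box `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   data bounding box padded by 5% of its span.
#' @param clip if `TRUE`, boundary tiles use their box-clipped area rather
#'   than density 0.
#' @return Numeric density vector (1/nm^2) with attributes
#'   `method = "voronoi"`, `area` (tile areas), `adjacency` (per-detection
#'   integer neighbour lists) and `boundary` (logical, tile touches the box).
#' @export
voronoi_density <- function(t, bbox = NULL, clip = FALSE) {
  coords <- if (is.matrix(t)) t else det_coords(t)
  if (ncol(coords) != 2)
    stop("voronoi_density supports 2D detection tables only")
  n <- nrow(coords)
  if (n < 3) stop("degeneracy error: need at least dim + 1 detections")
  if (is.null(bbox)) {
    rx <- range(coords[, 1]); ry <- range(coords[, 2])
    pad <- 0.05 * max(diff(rx), diff(ry), 1)
    bbox <- c(rx[1] - pad, rx[2] + pad, ry[1] - pad, ry[2] + pad)
  }
  # collapse exactly coincident detections: duplicates share their site's tile
  key <- paste(coords[, 1], coords[, 2])
  uniq <- !duplicated(key)
  map <- match(key, key[uniq])               # detection -> unique site
  upts <- coords[uniq, , drop = FALSE]
  if (nrow(upts) < 3 || qr(sweep(upts, 2, upts[1, ]))$rank < 2)
    stop("degeneracy error: detections are collinear")
  cells <- voronoi_cells_cpp(upts, as.numeric(bbox))

  area_u <- cells$area
  bnd_u <- cells$boundary
  area <- area_u[map]
  bnd <- bnd_u[map]
  f <- ifelse(!clip & bnd, 0, ifelse(area > 0, 1 / area, 0))

  # expand adjacency to original indices; coincident detections are mutually
  # adjacent and inherit their site's neighbours
  groups <- split(seq_len(n), map)
  adj <- vector("list", n)
  for (ui in seq_along(cells$neighbors)) {
    nb_sites <- cells$neighbors[[ui]]
    nb_det <- unlist(groups[as.character(nb_sites)], use.names = FALSE)
    for (i in groups[[as.character(ui)]]) {
      others <- setdiff(groups[[as.character(ui)]], i)
      adj[[i]] <- sort(c(nb_det, others))
    }
  }
  attr(f, "method") <- "voronoi"
  attr(f, "area") <- area
  attr(f, "adjacency") <- adj
  attr(f, "boundary") <- bnd
  f
}
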