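#' Pipeline configuration
#'
#' Collects every stage parameter of the standard workflow — optional
#' pre-filtering, clustering, per-cluster topology, statistics and radial
#' profile — together with either an input file or a simulation scenario,
#' and a master seed. Configurations round-trip losslessly through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param input path to a detection table, or `NULL` when simulating.
#' @param scenario a [scenario_config()] (used when `input` is `NULL`).
#' @param photophysics a [photophysics_config()].
#' @param min_photons intensity pre-filter in photons (`NULL` to skip).
#' @param link_dist consecutive-frame linking distance in nm (`NULL` to skip).
#' @param algorithm clustering algorithm tag (see [run_clustering()]).
#' @param cluster_params named list of clustering parameters.
#' @param pers_threshold persistence threshold in nm.
#' @param mu consensus weighting constant.
#' @param n_resamples consensus resamples.
#' @param max_dim maximum simplex dimension for the filtrations.
#' @param max_scale optional filtration cap in nm.
#' @param min_cluster_size smallest cluster analysed for topology.
#' @param bin_width radial profile bin width in nm.
#' @param want_holes,min_alpha topology filter applied before the radial
#'   profile.
#' @param seed master seed.
#' @param output_dir directory for result CSVs (`NULL`: nothing written).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, scenario = NULL,
                            photophysics = photophysics_config(),
                            min_photons = NULL, link_dist = NULL,
                            algorithm = "tomato",
                            cluster_params = list(r = 20, tau = 10),
                            pers_threshold = 15, mu = -log(0.1),
                            n_resamples = 100, max_dim = 2, max_scale = NULL,
                            min_cluster_size = 4, bin_width = 5,
                            want_holes = 1, min_alpha = 90,
                            seed = 1, output_dir = NULL) {
  if (is.null(input) && is.null(scenario))
    stop("config error: either an input table or a simulation scenario is required")
  structure(list(input = input, scenario = scenario, photophysics = photophysics,
                 min_photons = min_photons, link_dist = link_dist,
                 algorithm = algorithm, cluster_params = cluster_params,
                 pers_threshold = pers_threshold, mu = mu,
                 n_resamples = n_resamples, max_dim = max_dim,
                 max_scale = max_scale, min_cluster_size = min_cluster_size,
                 bin_width = bin_width, want_holes = want_holes,
                 min_alpha = min_alpha, seed = seed, output_dir = output_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- unclass(config)
  if (!is.null(plain$scenario)) {
    sc <- unclass(plain$scenario)
    if (!is.null(sc$centres)) sc$centres <- apply(sc$centres, 1, as.numeric,
                                                  simplify = FALSE)
    plain$scenario <- sc
  }
  if (!is.null(plain$photophysics)) plain$photophysics <- unclass(plain$photophysics)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$scenario)) {
    sc <- raw$scenario
    sc$field_size <- as.numeric(sc$field_size)
    if (!is.null(sc$centres)) sc$centres <- do.call(rbind, sc$centres)
    raw$scenario <- do.call(scenario_config, sc)
  }
  if (!is.null(raw$photophysics))
    raw$photophysics <- do.call(photophysics_config, raw$photophysics)
  raw$cluster_params <- lapply(raw$cluster_params, as.numeric)
  do.call(pipeline_config, raw)
}

#' Run the standard analysis pipeline
#'
#' Executes, deterministically for a given seed: (1) simulate or read the
#' detection table; (2) optional intensity filter and consecutive-frame
#' linking; (3) clustering; (4) per-cluster topology with the sub-sampled
#' consensus; (5) cluster statistics; (6) topology filter and averaged
#' radial profile. Each stage's parameters are recorded in the run log;
#' when `output_dir` is set, per-stage CSV outputs and a YAML run manifest
#' are written as each stage completes.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result` with `detections`, `truth`
#'   (when simulated), `clustering`, `topology`, `stats`, `selected`
#'   (labels passing the topology filter), `radial` and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list(seed = config$seed)
  outdir <- config$output_dir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(name, df) {
    if (!is.null(outdir))
      utils::write.csv(df, file.path(outdir, paste0(name, ".csv")),
                       row.names = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- input ---------------------------------------------------------------
  truth <- NULL
  det <- stage("input", {
    if (!is.null(config$input)) {
      if (!file.exists(config$input))
        stop("input file not found: ", config$input)
      read_detections(config$input)
    } else {
      sim <- simulate_smlm(config$scenario, config$photophysics,
                           seed = derive_seed(config$seed, 1))
      truth <- sim$truth
      sim$detections
    }
  })
  log$input <- list(n_detections = nrow(det), simulated = is.null(config$input))

  # --- pre-processing ------------------------------------------------------
  if (!is.null(config$min_photons)) {
    det <- stage("intensity_filter", filter_by_intensity(det, config$min_photons))
    log$intensity_filter <- list(min_photons = config$min_photons,
                                 n_detections = nrow(det))
  }
  if (!is.null(config$link_dist)) {
    det <- stage("frame_linking", link_consecutive_frames(det, config$link_dist))
    log$frame_linking <- list(link_dist = config$link_dist,
                              n_detections = nrow(det))
  }
  emit("detections", as.data.frame(det))

  # --- clustering ----------------------------------------------------------
  cl <- stage("clustering",
              run_clustering(det, config$algorithm, config$cluster_params))
  log$clustering <- c(list(algorithm = config$algorithm), config$cluster_params,
                      list(n_clusters = cl$n_clusters))
  emit("labels", data.frame(id = seq_along(cl$labels), cluster = cl$labels))
  if (!is.null(cl$diagram)) emit("tomato_diagram", cl$diagram)

  # --- topology ------------------------------------------------------------
  set.seed(derive_seed(config$seed, 2))
  topo <- stage("topology",
                per_cluster_topology(det, cl,
                                     pers_threshold = config$pers_threshold,
                                     mu = config$mu,
                                     n_resamples = config$n_resamples,
                                     max_dim = config$max_dim,
                                     max_scale = config$max_scale,
                                     min_size = config$min_cluster_size))
  log$topology <- topo$parameters
  emit("topology", topo$table)

  # --- statistics ----------------------------------------------------------
  field_area <- if (!is.null(config$scenario))
    prod(config$scenario$field_size) else prod(apply(det_coords(det), 2,
                                                     function(v) diff(range(v))))
  st <- stage("stats", cluster_stats(det, cl, field_area))
  log$stats <- list(field_area = field_area, n_clusters = st$n_clusters,
                    mean_area = st$mean_area)
  emit("cluster_stats", st$clusters)

  # --- topology filter + radial profile ------------------------------------
  want <- c(holes = config$want_holes)
  if (config$max_dim >= 3) want <- c(want, voids = 0)
  selected <- stage("topology_filter",
                    filter_clusters_by_topology(topo, want = want,
                                                min_alpha = config$min_alpha))
  radial <- NULL
  if (length(selected)) {
    coords <- det_coords(det)
    pts <- lapply(selected, function(L) coords[cl$labels == L, , drop = FALSE])
    radial <- stage("radial", radial_profile(pts, bin_width = config$bin_width))
    emit("radial_profile", data.frame(mid = radial$mid,
                                      frequency = radial$frequency))
  }
  log$radial <- list(selected = selected,
                     peak = if (!is.null(radial)) radial$peak else NA_real_)

  if (!is.null(outdir)) yaml::write_yaml(log, file.path(outdir, "run_manifest.yaml"))
  structure(list(detections = det, truth = truth, clustering = cl,
                 topology = topo, stats = st, selected = selected,
                 radial = radial, log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  detections: %d | clusters: %d | analysed for topology: %d\n",
              nrow(x$detections), x$clustering$n_clusters, nrow(x$topology$table)))
  cat(sprintf("  clusters passing topology filter: %d\n", length(x$selected)))
  if (!is.null(x$radial))
    cat(sprintf("  radial profile peak: %g nm\n", x$radial$peak))
  invisible(x)
}

#' Miniature deterministic test datasets
#'
#' Builds the small synthetic datasets used throughout the test suite and
#' examples: down-scaled versions of the simulation scenarios (at most ~500
#' detections each), the two-circles illustration (points evenly spaced on
#' two circles, in arbitrary units) and the regular hexagon with its
#' analytically known H1 feature.
#'
#' @param seed integer seed.
#' @return A named list: `csr`, `gaussian`, `ring` (each a
#'   [simulate_smlm()] result), `two_circles` (coordinate matrix),
#'   `hexagon` (coordinate matrix).
#' @export
make_fixtures <- function(seed = 1) {
  pc <- photophysics_config()
  csr <- simulate_smlm(scenario_config("csr", field_size = c(1000, 1000),
                                       n_molecules = 60),
                       pc, seed = derive_seed(seed, 11))
  gauss <- simulate_smlm(scenario_config("gaussian", field_size = c(1000, 1000),
                                         n_clusters = 4, molecules_per_cluster = 10,
                                         cluster_sd = 10, margin = 150),
                         pc, seed = derive_seed(seed, 12))
  ring <- simulate_smlm(scenario_config("ring", field_size = c(1200, 1200),
                                        n_clusters = 4, molecules_per_cluster = 16,
                                        ring_radius = 60, margin = 200),
                        pc, seed = derive_seed(seed, 13))
  circle <- function(n, radius, centre) {
    ang <- 2 * pi * (seq_len(n) - 1) / n
    cbind(x = centre[1] + radius * cos(ang), y = centre[2] + radius * sin(ang))
  }
  two_circles <- rbind(circle(12, 20, c(0, 0)), circle(9, 10, c(55, 0)))
  hexagon <- circle(6, 10, c(0, 0))
  list(csr = csr, gaussian = gauss, ring = ring,
       two_circles = two_circles, hexagon = hexagon)
}
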