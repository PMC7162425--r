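#' Photophysics model for simulated dSTORM detections
#'
#' Parameters of the blinking/detection model used by [simulate_detections()]:
#' each molecule carries a Poisson-distributed number of fluorophores (mean
#' `mean_fluors_per_molecule`); each fluorophore blinks a geometric number of
#' times (support 1, 2, ..., mean `1/p_dark`); each blink is detected with
#' probability `detection_rate`; a detected blink is localized at the
#' molecule position plus isotropic normal error whose standard deviation is
#' drawn from a log-normal distribution (`uncertainty_meanlog`,
#' `uncertainty_sdlog`, on the log scale, in nm) and reported as the
#' detection's localization uncertainty. Finally uniformly distributed false
#' detections are appended so that they make up `noise_fraction` of the
#' table. The defaults are the experimentally calibrated values for
#' AlexaFluor647 dSTORM imaging (median localization SD about 16.4 nm).
#'
#' @param p_dark probability of transition to the dark state per blink
#'   (default 0.5, so a mean of 2 blinks per fluorophore).
#' @param mean_fluors_per_molecule mean label stoichiometry (default 5).
#' @param uncertainty_meanlog,uncertainty_sdlog log-scale parameters of the
#'   localization-SD distribution (defaults 2.8 and 0.28).
#' @param detection_rate fraction of blinks that yield a detection (0.70).
#' @param noise_fraction fraction of the final table that is false
#'   detections (0.10).
#' @return A list of class `photophysics_config`.
#' @export
photophysics_config <- function(p_dark = 0.5, mean_fluors_per_molecule = 5,
                                uncertainty_meanlog = 2.8, uncertainty_sdlog = 0.28,
                                detection_rate = 0.70, noise_fraction = 0.10) {
  stopifnot(p_dark > 0, p_dark <= 1, mean_fluors_per_molecule >= 0,
            is.finite(uncertainty_meanlog), is.finite(uncertainty_sdlog),
            uncertainty_sdlog >= 0, detection_rate >= 0, detection_rate <= 1,
            noise_fraction >= 0, noise_fraction < 1)
  structure(list(p_dark = p_dark,
                 mean_fluors_per_molecule = mean_fluors_per_molecule,
                 uncertainty_meanlog = uncertainty_meanlog,
                 uncertainty_sdlog = uncertainty_sdlog,
                 detection_rate = detection_rate,
                 noise_fraction = noise_fraction),
            class = "photophysics_config")
}

#' Molecule placement scenarios
#'
#' Describes how true molecule positions are laid out before the
#' photophysics model is applied: complete spatial randomness (`"csr"`),
#' isotropic Gaussian clusters (`"gaussian"`), pairs of Gaussian clusters at
#' a fixed centre separation (`"gaussian_pair"`), or circular rings with
#' molecules evenly spaced on the circumference (`"ring"`).
#'
#' @param kind one of `"csr"`, `"gaussian"`, `"gaussian_pair"`, `"ring"`.
#' @param field_size numeric vector of per-axis field extents in nm (length
#'   2 or 3; a scalar is recycled to 2D).
#' @param n_molecules total molecules for `"csr"`.
#' @param n_clusters number of clusters (or ring structures, or cluster
#'   pairs for `"gaussian_pair"`).
#' @param molecules_per_cluster molecules per cluster/ring.
#' @param cluster_sd isotropic SD of Gaussian clusters in nm.
#' @param ring_radius ring radius in nm.
#' @param separation centre separation in nm for `"gaussian_pair"`.
#' @param centres optional matrix of cluster centres (nm); by default
#'   centres are placed on a jittered grid with a margin so that structures
#'   stay inside the field.
#' @param margin margin in nm kept between grid-placed centres and the field
#'   edge.
#' @param ring_orientation for 3D rings: `"xy"` (default) places rings in
#'   xy-planes, `"random"` draws a uniformly random plane per ring.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(kind = c("csr", "gaussian", "gaussian_pair", "ring"),
                            field_size = c(2000, 2000), n_molecules = 100,
                            n_clusters = 4, molecules_per_cluster = 30,
                            cluster_sd = 10, ring_radius = 60, separation = 60,
                            centres = NULL, margin = 200,
                            ring_orientation = c("xy", "random")) {
  kind <- match.arg(kind)
  if (length(field_size) == 1) field_size <- rep(field_size, 2)
  stopifnot(length(field_size) %in% c(2, 3), all(field_size > 0),
            cluster_sd > 0, ring_radius > 0, separation > 0)
  if (!is.null(centres)) {
    centres <- as.matrix(centres)
    if (ncol(centres) != length(field_size))
      stop("configuration error: centres dimensionality does not match field")
    if (any(sweep(centres, 2, field_size) > 0) || any(centres < 0))
      stop("configuration error: cluster centre outside field")
  }
  structure(list(kind = kind, field_size = field_size, n_molecules = n_molecules,
                 n_clusters = n_clusters,
                 molecules_per_cluster = molecules_per_cluster,
                 cluster_sd = cluster_sd, ring_radius = ring_radius,
                 separation = separation, centres = centres, margin = margin,
                 ring_orientation = match.arg(ring_orientation)),
            class = "scenario_config")
}

# evenly spread centres on a jittered grid, deterministic given the RNG state
place_centres <- function(sc, k) {
  d <- length(sc$field_size)
  lo <- rep(sc$margin, d)
  hi <- sc$field_size - sc$margin
  if (any(hi <= lo)) stop("configuration error: margin too large for field")
  per_axis <- ceiling(k^(1 / d))
  axes <- lapply(seq_len(d), function(a) {
    s <- seq(lo[a], hi[a], length.out = per_axis + 1)
    (s[-1] + s[-length(s)]) / 2
  })
  grid <- as.matrix(expand.grid(axes))[seq_len(k), , drop = FALSE]
  jit <- (hi - lo) / (4 * per_axis)
  grid + matrix(runif(k * d, -1, 1), k, d) %*% diag(jit, d, d)
}

#' Place true molecule positions for a scenario
#'
#' Draws molecule positions according to the scenario layout. Uses the
#' current R random number generator; call `set.seed()` (or go through
#' [simulate_smlm()]) for reproducibility.
#'
#' @param sc a [scenario_config()].
#' @return A list with `positions` (matrix, nm) and `labels` (integer
#'   structure labels; 0 for CSR molecules).
#' @export
place_molecules <- function(sc) {
  stopifnot(inherits(sc, "scenario_config"))
  d <- length(sc$field_size)
  if (sc$kind == "csr") {
    n <- sc$n_molecules
    pos <- vapply(seq_len(d), function(a) runif(n, 0, sc$field_size[a]),
                  numeric(n))
    if (n == 1) pos <- matrix(pos, 1)
    return(list(positions = pos, labels = integer(n)))
  }
  k <- sc$n_clusters
  m <- sc$molecules_per_cluster
  if (sc$kind == "gaussian_pair") {
    # each "cluster pair" contributes two clusters separated by `separation`
    pair_centres <- if (is.null(sc$centres)) place_centres(sc, k) else sc$centres
    centres <- NULL
    for (p in seq_len(k)) {
      theta <- runif(1, 0, 2 * pi)
      u <- if (d == 2) c(cos(theta), sin(theta)) else {
        z <- rnorm(3); z / sqrt(sum(z^2))
      }
      centres <- rbind(centres,
                       pair_centres[p, ] - u * sc$separation / 2,
                       pair_centres[p, ] + u * sc$separation / 2)
    }
    k <- 2L * k
  } else {
    centres <- if (is.null(sc$centres)) place_centres(sc, k) else sc$centres
  }
  pos <- NULL
  labels <- integer(0)
  for (c_i in seq_len(k)) {
    if (sc$kind == "ring") {
      ang <- 2 * pi * (seq_len(m) - 1) / m
      circ <- cbind(sc$ring_radius * cos(ang), sc$ring_radius * sin(ang))
      if (d == 3) {
        circ <- cbind(circ, 0)
        if (sc$ring_orientation == "random") {
          z <- rnorm(3); z <- z / sqrt(sum(z^2))     # plane normal
          a <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
          e1 <- a - sum(a * z) * z; e1 <- e1 / sqrt(sum(e1^2))
          e2 <- c(z[2] * e1[3] - z[3] * e1[2],
                  z[3] * e1[1] - z[1] * e1[3],
                  z[1] * e1[2] - z[2] * e1[1])
          circ <- circ[, 1] %o% e1 + circ[, 2] %o% e2
        }
      }
      pts <- sweep(circ, 2, centres[c_i, ], "+")
    } else {
      pts <- matrix(rnorm(m * d, sd = sc$cluster_sd), m, d)
      pts <- sweep(pts, 2, centres[c_i, ], "+")
    }
    pos <- rbind(pos, pts)
    labels <- c(labels, rep.int(c_i, m))
  }
  colnames(pos) <- c("x", "y", "z")[seq_len(d)]
  list(positions = pos, labels = labels)
}

#' Simulate dSTORM detections from molecule positions
#'
#' Applies the photophysics model of [photophysics_config()] to a set of
#' molecule positions and returns a detection table plus ground truth. Uses
#' the current RNG state.
#'
#' @param molecules a list as returned by [place_molecules()], or a bare
#'   position matrix (all labels 1).
#' @param pc a [photophysics_config()].
#' @param field_size per-axis field extents in nm for placing false
#'   detections (defaults to the bounding box of the molecules when `NULL`).
#' @return A list with `detections` (a [detection_table()]) and `truth`, a
#'   list with per-detection `labels` (0 = false detection), `molecule`
#'   (generating molecule index, NA for noise), per-molecule `positions` and
#'   `molecule_labels`, and `stats` (counts of molecules, fluorophores,
#'   blinks, detected blinks and noise detections).
#' @export
simulate_detections <- function(molecules, pc = photophysics_config(),
                                field_size = NULL) {
  if (is.matrix(molecules)) molecules <- list(positions = molecules,
                                              labels = rep.int(1L, nrow(molecules)))
  pos <- molecules$positions
  if (is.null(pos) || nrow(pos) == 0) stop("empty molecule list")
  nmol <- nrow(pos)
  d <- ncol(pos)
  if (is.null(field_size)) field_size <- apply(pos, 2, max)

  nf <- rpois(nmol, pc$mean_fluors_per_molecule)      # fluorophores/molecule
  total_f <- sum(nf)
  mol_of_f <- rep.int(seq_len(nmol), nf)
  # blinks per fluorophore: geometric on {1, 2, ...}, mean 1/p_dark
  blinks <- if (total_f) rgeom(total_f, pc$p_dark) + 1L else integer(0)
  total_b <- sum(blinks)
  mol_of_b <- rep.int(mol_of_f, blinks)
  detected <- if (total_b) runif(total_b) < pc$detection_rate else logical(0)
  mol_idx <- mol_of_b[detected]
  n_true <- length(mol_idx)

  sigma <- rlnorm(n_true, pc$uncertainty_meanlog, pc$uncertainty_sdlog)
  err <- matrix(rnorm(n_true * d), n_true, d) * sigma
  xyz <- pos[mol_idx, , drop = FALSE] + err

  n_noise <- round(pc$noise_fraction / (1 - pc$noise_fraction) * n_true)
  if (n_noise > 0) {
    noise_xyz <- vapply(seq_len(d), function(a) runif(n_noise, 0, field_size[a]),
                        numeric(n_noise))
    if (n_noise == 1) noise_xyz <- matrix(noise_xyz, 1)
    noise_sigma <- rlnorm(n_noise, pc$uncertainty_meanlog, pc$uncertainty_sdlog)
    xyz <- rbind(xyz, noise_xyz)
    sigma <- c(sigma, noise_sigma)
  }
  labels <- c(molecules$labels[mol_idx], integer(n_noise))
  mol_col <- c(mol_idx, rep(NA_integer_, n_noise))

  det <- detection_table(x = xyz[, 1], y = xyz[, 2],
                         z = if (d == 3) xyz[, 3] else NULL,
                         frame = sample.int(10000L, n_true + n_noise, replace = TRUE),
                         uncertainty = sigma)
  truth <- list(labels = labels, molecule = mol_col,
                positions = pos, molecule_labels = molecules$labels,
                stats = list(n_molecules = nmol, n_fluorophores = total_f,
                             n_blinks = total_b, n_detected = n_true,
                             n_noise = n_noise))
  list(detections = det, truth = truth)
}

#' Simulate a complete scenario
#'
#' Convenience wrapper: seeds the RNG, places molecules and applies the
#' photophysics model. The same `sc`, `pc` and `seed` always give an
#' identical result.
#'
#' @param sc a [scenario_config()].
#' @param pc a [photophysics_config()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return As [simulate_detections()].
#' @export
simulate_smlm <- function(sc, pc = photophysics_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  simulate_detections(place_molecules(sc), pc, field_size = sc$field_size)
}

#' Generate a benchmark suite of simulated datasets
#'
#' Simulates `reps` independent replicates of each scenario, with a
#' deterministic per-(scenario, replicate) seed stream derived from the
#' master seed, and attaches a manifest for batch evaluation.
#'
#' @param scenarios a named list of [scenario_config()] objects.
#' @param reps replicates per scenario (>= 1).
#' @param pc a [photophysics_config()].
#' @param seed master integer seed.
#' @return A list with `datasets` (list of `simulate_smlm()` results) and
#'   `manifest` (data.frame: scenario, rep, seed, n_detections).
#' @export
generate_benchmark_suite <- function(scenarios, reps = 20,
                                     pc = photophysics_config(), seed = 1) {
  stopifnot(reps >= 1, length(scenarios) >= 1)
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  datasets <- list()
  manifest <- NULL
  for (si in seq_along(scenarios)) {
    for (r in seq_len(reps)) {
      sub <- derive_seed(seed, si, r)
      key <- sprintf("%s_rep%d", names(scenarios)[si], r)
      datasets[[key]] <- simulate_smlm(scenarios[[si]], pc, seed = sub)
      manifest <- rbind(manifest,
                        data.frame(scenario = names(scenarios)[si], rep = r,
                                   seed = sub,
                                   n_detections = nrow(datasets[[key]]$detections)))
    }
  }
  list(datasets = datasets, manifest = manifest)
}

#' Deterministic sub-seed fan-out
#'
#' Derives reproducible child seeds from a master seed and an index path
#' (e.g. scenario number, replicate number) via an iterated linear
#' congruence, keeping results within the 32-bit integer range. Used by
#' [generate_benchmark_suite()] and [run_pipeline()] so that every
#' stochastic step has its own stream while remaining a pure function of the
#' master seed.
#'
#' @param seed master integer seed.
#' @param ... integer index path.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + 7919 * k) %% 2147483647
  as.integer(s)
}
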