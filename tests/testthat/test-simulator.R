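test_that("scenario and photophysics configurations validate inputs", {
  sc <- scenario_config("ring", field_size = 1500, n_clusters = 3)
  expect_equal(sc$field_size, c(1500, 1500))
  expect_error(scenario_config("gaussian", cluster_sd = 0), "cluster_sd")
  expect_error(scenario_config("csr", centres = cbind(1, 1, 1)),
               "dimensionality")
  expect_error(scenario_config("gaussian", field_size = c(100, 100),
                               centres = cbind(200, 50)), "outside")

  pc <- photophysics_config()
  expect_equal(pc$p_dark, 0.5)
  expect_equal(pc$mean_fluors_per_molecule, 5)
  expect_equal(pc$uncertainty_meanlog, 2.8)
  expect_equal(pc$uncertainty_sdlog, 0.28)
  expect_equal(pc$detection_rate, 0.7)
  expect_equal(pc$noise_fraction, 0.1)
  expect_error(photophysics_config(detection_rate = 1.5), "detection_rate")
  expect_error(photophysics_config(noise_fraction = 1), "noise_fraction")
})

test_that("molecule placement respects each scenario's geometry", {
  sc_ring <- scenario_config("ring", field_size = c(2000, 2000),
                             n_clusters = 3, molecules_per_cluster = 12,
                             ring_radius = 60, margin = 200)
  set.seed(1)
  mol <- place_molecules(sc_ring)
  expect_equal(nrow(mol$positions), 36L)
  expect_equal(mol$labels, rep(1:3, each = 12))
  for (L in 1:3) {
    pts <- mol$positions[mol$labels == L, ]
    cen <- colMeans(pts)
    expect_equal(sqrt(rowSums(sweep(pts, 2, cen)^2)), rep(60, 12),
                 tolerance = 1e-8)
  }

  sc_pair <- scenario_config("gaussian_pair", field_size = c(2000, 2000),
                             n_clusters = 2, molecules_per_cluster = 50,
                             cluster_sd = 5, separation = 80, margin = 200)
  set.seed(2)
  mp <- place_molecules(sc_pair)
  expect_equal(sort(unique(mp$labels)), 1:4)
  cents <- t(sapply(1:4, function(L) colMeans(mp$positions[mp$labels == L, ])))
  # paired clusters sit ~80 nm apart (sample means of sd-5 clusters of 50)
  expect_equal(sqrt(sum((cents[1, ] - cents[2, ])^2)), 80, tolerance = 0.1)
  expect_equal(sqrt(sum((cents[3, ] - cents[4, ])^2)), 80, tolerance = 0.1)

  sc_csr <- scenario_config("csr", field_size = c(500, 800), n_molecules = 200)
  set.seed(3)
  mc <- place_molecules(sc_csr)
  expect_true(all(mc$positions[, 1] >= 0 & mc$positions[, 1] <= 500))
  expect_true(all(mc$positions[, 2] >= 0 & mc$positions[, 2] <= 800))
  expect_equal(mc$labels, integer(200))
})

test_that("the photophysics model is reproducible and self-consistent", {
  sc <- scenario_config("gaussian", field_size = c(1000, 1000),
                        n_clusters = 2, molecules_per_cluster = 20,
                        cluster_sd = 15, margin = 150)
  a <- simulate_smlm(sc, seed = 99)
  b <- simulate_smlm(sc, seed = 99)
  expect_identical(a$detections, b$detections)
  expect_identical(a$truth, b$truth)

  s <- a$truth$stats
  expect_equal(s$n_molecules, 40L)
  expect_gte(s$n_blinks, s$n_fluorophores)   # every fluorophore blinks >= once
  expect_lte(s$n_detected, s$n_blinks)
  expect_equal(nrow(a$detections), s$n_detected + s$n_noise)
  expect_equal(s$n_noise, round(0.1 / 0.9 * s$n_detected))
  expect_equal(sum(a$truth$labels == 0), s$n_noise)
  expect_true(all(is.na(a$truth$molecule[a$truth$labels == 0])))
  expect_true(all(a$detections$uncertainty > 0))
  expect_true(all(a$detections$frame >= 1))
})

test_that("detection counts scale with the stated rates at moderate size", {
  sc <- scenario_config("csr", field_size = c(10000, 10000), n_molecules = 2000)
  s <- simulate_smlm(sc, seed = 7)$truth$stats
  # Poisson(5) fluorophores, geometric blinks of mean 2, Binomial(0.7) kept
  expect_equal(s$n_fluorophores / s$n_molecules, 5, tolerance = 0.1)
  expect_equal(s$n_blinks / s$n_fluorophores, 2, tolerance = 0.1)
  expect_equal(s$n_detected / s$n_blinks, 0.7, tolerance = 0.05)
  # log-normal localization uncertainty: median exp(2.8) ~ 16.4 nm
  det <- simulate_smlm(sc, seed = 8)$detections
  expect_equal(median(det$uncertainty), exp(2.8), tolerance = 0.05)
})

test_that("benchmark suites have deterministic per-replicate seed streams", {
  sc <- scenario_config("gaussian", field_size = c(800, 800), n_clusters = 2,
                        molecules_per_cluster = 8, margin = 150)
  s1 <- generate_benchmark_suite(list(g = sc), reps = 3, seed = 5)
  s2 <- generate_benchmark_suite(list(g = sc), reps = 3, seed = 5)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$datasets$g_rep2, s2$datasets$g_rep2)
  expect_equal(nrow(s1$manifest), 3L)
  # replicates differ from one another
  expect_false(identical(s1$datasets$g_rep1$detections,
                         s1$datasets$g_rep2$detections))
  # seed fan-out is a pure function with distinct streams
  expect_identical(derive_seed(1, 2, 3), derive_seed(1, 2, 3))
  expect_false(derive_seed(1, 2, 3) == derive_seed(1, 3, 2))
})
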