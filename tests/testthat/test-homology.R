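test_that("regular polygons have the analytic Rips H1 feature", {
  # m evenly spaced points on a circle of radius R: the hole is born when
  # consecutive points connect (2 R sin(pi/m)) and dies when the polygon is
  # triangulated by chords skipping ceiling(m/3) vertices
  for (m in 5:9) {
    R <- 10
    pd <- rips_persistence(regular_polygon(m, R), max_dim = 2)
    h1 <- pd[pd$dimension == 1, ]
    expect_equal(nrow(h1), 1L)
    expect_equal(h1$birth, 2 * R * sin(pi / m), tolerance = 1e-12)
    expect_equal(h1$death, 2 * R * sin(ceiling(m / 3) * pi / m),
                 tolerance = 1e-12)
  }
  # hexagon: birth 10, death 10 * sqrt(3)
  pd <- rips_persistence(regular_polygon(6, 10))
  h1 <- pd[pd$dimension == 1, ]
  expect_equal(c(h1$birth, h1$death), c(10, 10 * sqrt(3)), tolerance = 1e-12)
  # H0: five merges at the side length, one essential component
  h0 <- pd[pd$dimension == 0, ]
  expect_equal(sum(is.infinite(h0$death)), 1L)
  expect_equal(h0$death[is.finite(h0$death)], rep(10, 5), tolerance = 1e-12)
})

test_that("production persistence equals full GF(2) reduction, 2D", {
  set.seed(21)
  for (rep in 1:6) {
    n <- sample(6:12, 1)
    pts <- matrix(runif(2 * n, 0, 50), ncol = 2)
    expect_equal(pd_canon(rips_persistence(pts, max_dim = 2)),
                 pd_canon(oracle_rips(pts, max_dim = 2)))
    # and with a restrictive filtration cap
    expect_equal(pd_canon(rips_persistence(pts, max_scale = 22, max_dim = 2)),
                 pd_canon(oracle_rips(pts, max_scale = 22, max_dim = 2)))
  }
})

test_that("production persistence equals full GF(2) reduction, 3D with H2", {
  set.seed(22)
  for (rep in 1:4) {
    n <- sample(6:10, 1)
    pts <- matrix(runif(3 * n, 0, 50), ncol = 3)
    expect_equal(pd_canon(rips_persistence(pts, max_dim = 3)),
                 pd_canon(oracle_rips(pts, max_dim = 3)))
  }
  # octahedron: one void, born at the edge length, dying at the diameter
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  pd <- rips_persistence(oct, max_dim = 3)
  h2 <- pd[pd$dimension == 2, ]
  expect_equal(c(h2$birth, h2$death), c(sqrt(2), 2), tolerance = 1e-12)
  expect_equal(pd_canon(pd), pd_canon(oracle_rips(oct, max_dim = 3)))
})

test_that("degenerate inputs are handled: duplicates, tiny sets, guards", {
  # coincident points create zero-persistence pairs, which are dropped
  pts <- rbind(c(0, 0), c(0, 0), c(30, 0))
  pd <- rips_persistence(pts)
  expect_equal(pd_canon(pd), pd_canon(oracle_rips(pts)))
  expect_true(all(pd$death > pd$birth))

  one <- rips_persistence(matrix(c(5, 5), ncol = 2))
  expect_equal(nrow(one), 1L)
  expect_equal(one$dimension, 0L)
  expect_true(is.infinite(one$death))

  expect_error(rips_persistence(matrix(0, 0, 2)), "at least one")
  expect_error(rips_persistence(matrix(runif(2 * 2600), ncol = 2)), "2500")
  expect_error(rips_persistence(regular_polygon(6), max_dim = 4), "max_dim")
  expect_error(rips_persistence(regular_polygon(6), max_scale = -1),
               "max_scale")
})

test_that("threshold_diagram counts persistent features per dimension", {
  fx <- make_fixtures(1)
  pd <- rips_persistence(fx$two_circles, max_dim = 2)
  cfg <- threshold_diagram(pd, 8)
  expect_s3_class(cfg, "topo_configuration")
  expect_equal(unclass(cfg)[["holes"]], 2L, ignore_attr = TRUE)
  expect_false("voids" %in% names(cfg))  # 2D analysis carries no void count
  # a huge threshold keeps only never-dying features
  expect_equal(unclass(threshold_diagram(pd, 1e9))[["holes"]], 0L)
  expect_equal(attr(threshold_diagram(pd, 1e9), "n_components"), 1L)
  expect_error(threshold_diagram(pd, -1), ">= 0")

  pd3 <- rips_persistence(cbind(regular_polygon(8), 0), max_dim = 3)
  cfg3 <- threshold_diagram(pd3, 5)
  expect_named(cfg3, c("holes", "voids"))
  expect_equal(as.integer(cfg3), c(1L, 0L))
})

test_that("sampling weights give the stated 10:1 extreme ratio", {
  unc <- c(5, 12, 30)
  w <- sampling_weights(unc)
  raw <- attr(w, "raw")
  expect_equal(raw[1] / raw[3], 10)            # mu = -log(0.1) exactly
  expect_equal(sum(w), 1)
  expect_true(all(diff(w) < 0))                # more precise -> more likely
  # equal uncertainties mean uniform weights
  expect_equal(as.numeric(sampling_weights(rep(7, 4))), rep(0.25, 4))
  # mu = 0 disables the weighting
  expect_equal(as.numeric(sampling_weights(unc, mu = 0)), rep(1 / 3, 3))
  expect_error(sampling_weights(numeric(0)), "at least one")
  expect_error(sampling_weights(c(1, -1)), "negative")
  expect_error(sampling_weights(1:3, mu = -1), "mu")
})

test_that("subsample_consensus is reproducible and finds clean topology", {
  fx <- make_fixtures(1)
  ring <- do.call(rbind, replicate(6, fx$two_circles[1:12, ], simplify = FALSE)) +
    matrix(rnorm(144, sd = 1), ncol = 2)
  set.seed(31)
  a <- subsample_consensus(ring, pers_threshold = 8, n_resamples = 50)
  set.seed(31)
  b <- subsample_consensus(ring, pers_threshold = 8, n_resamples = 50)
  expect_identical(a$table, b$table)
  expect_equal(unclass(a$consensus)[["holes"]], 1L)
  expect_gt(a$alpha, 90)
  expect_equal(sum(a$table), 50)

  # weighting: detections with tiny uncertainty dominate the resamples
  set.seed(32)
  unc <- c(rep(1, 12), rep(1000, 12))
  pts <- rbind(fx$two_circles[1:12, ],
               cbind(rnorm(12, 500, 1), rnorm(12, 500, 1)))
  cons <- subsample_consensus(pts, uncertainties = unc, pers_threshold = 8,
                              n_resamples = 40, max_scale = 50)
  expect_equal(unclass(cons$consensus)[["holes"]], 1L)
})

test_that("per_cluster_topology analyses every cluster and records skips", {
  fx <- make_fixtures(1)
  big <- do.call(rbind, replicate(5, fx$two_circles[1:12, ], simplify = FALSE)) +
    matrix(rnorm(120, sd = 1), ncol = 2)
  pts <- rbind(big, big + 300, cbind(600, 600), cbind(c(900, 901), c(0, 1)))
  labels <- c(rep(1L, 60), rep(2L, 60), 0L, 3L, 3L)
  t <- detection_table(pts[, 1], pts[, 2],
                       uncertainty = rep(10, nrow(pts)))
  set.seed(33)
  topo <- per_cluster_topology(t, labels, pers_threshold = 8,
                               n_resamples = 30, min_size = 4)
  expect_equal(topo$table$label, c(1L, 2L))
  expect_equal(topo$table$holes_full, c(1L, 1L))
  expect_equal(topo$table$holes_consensus, c(1L, 1L))
  expect_match(topo$skipped[["3"]], "below min_size")
  expect_false("0" %in% names(topo$skipped))   # noise is never analysed
  expect_s3_class(topo$diagrams[["1"]], "persistence_diagram")
  expect_equal(topo$parameters$pers_threshold, 8)
})
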