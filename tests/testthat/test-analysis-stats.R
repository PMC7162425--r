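test_that("cluster_stats measures convex hulls and field densities", {
  # unit square plus an interior point: hull area 100^2, centroid known
  sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100), c(50, 50))
  tri <- rbind(c(200, 0), c(260, 0), c(200, 80))
  pts <- rbind(sq, tri, c(500, 500))
  labels <- c(rep(1L, 5), rep(2L, 3), 0L)
  st <- cluster_stats(pts, labels, field_area = 1000 * 1000)
  expect_equal(st$n_clusters, 2L)
  expect_equal(st$clusters$area, c(10000, 60 * 80 / 2))
  expect_equal(st$clusters$centroid_x, c(50, 220))
  expect_equal(st$mean_area, (10000 + 2400) / 2)
  # 2 clusters in 10^6 nm^2 = 2 clusters per um^2
  expect_equal(st$cluster_density, 2)
  # fewer than dim + 1 detections: measure 0
  st2 <- cluster_stats(rbind(c(0, 0), c(10, 0)), c(1L, 1L), field_area = 100)
  expect_equal(st2$clusters$area, 0)
  expect_error(cluster_stats(pts, labels, field_area = 0), "field_area")
})

test_that("3D hulls have exact volumes for known solids", {
  cube <- as.matrix(expand.grid(x = c(0, 50), y = c(0, 50), z = c(0, 50)))
  st <- cluster_stats(cube, rep(1L, 8), field_area = 1e9)
  expect_equal(st$clusters$area, 50^3)
  # regular tetrahedron with vertices on alternating cube corners:
  # volume = edge^3 / (6 sqrt(2)), edge = 50 sqrt(2)
  tet <- rbind(c(0, 0, 0), c(50, 50, 0), c(50, 0, 50), c(0, 50, 50))
  st2 <- cluster_stats(tet, rep(1L, 4), field_area = 1e9)
  expect_equal(st2$clusters$area, (50 * sqrt(2))^3 / (6 * sqrt(2)))
  # interior points change nothing
  jit <- rbind(cube, cbind(runif(20, 10, 40), runif(20, 10, 40),
                           runif(20, 10, 40)))
  st3 <- cluster_stats(jit, rep(1L, 28), field_area = 1e9)
  expect_equal(st3$clusters$area, 50^3)
  # coplanar 3D points have zero volume
  flat <- cbind(regular_polygon(8, 20), 0)
  expect_equal(cluster_stats(flat, rep(1L, 8), field_area = 1e9)$clusters$area,
               0, tolerance = 1e-9)
})

test_that("radial profiles peak at the ring radius for exact rings", {
  ring <- regular_polygon(36, R = 60)
  rp <- radial_profile(ring, bin_width = 5, max_radius = 80)
  expect_equal(rp$peak, 57.5)                 # exact radii fall in (55, 60]
  expect_equal(sum(rp$frequency), 1)
  # cluster-wise normalization: a huge cluster cannot drown a small one
  small <- regular_polygon(8, R = 20)
  rp2 <- radial_profile(list(ring, small), bin_width = 5, max_radius = 80)
  expect_equal(rp2$n_clusters, 2L)
  expect_equal(rp2$frequency[rp2$mid == 57.5], 0.5)
  expect_equal(rp2$frequency[rp2$mid == 17.5], 0.5)
  expect_equal(rp2$peak, 17.5)                # ties go to the smaller radius
  expect_error(radial_profile(ring, bin_width = 0), "bin width")
  expect_error(radial_profile(list()), "at least one")
})

test_that("topology filter selects single-hole clusters above the agreement bar", {
  topo <- list(table = data.frame(label = 1:4,
                                  n_detections = c(50, 60, 70, 80),
                                  holes_full = c(1L, 1L, 0L, 2L),
                                  holes_consensus = c(1L, 1L, 0L, 2L),
                                  alpha = c(95, 90, 99, 97)))
  class(topo) <- "cluster_topology"
  # alpha must strictly exceed min_alpha; config must match exactly
  expect_equal(filter_clusters_by_topology(topo, c(holes = 1), 90), 1L)
  expect_equal(filter_clusters_by_topology(topo, c(holes = 2), 90), 4L)
  expect_equal(filter_clusters_by_topology(topo, c(holes = 1), 89),
               c(1L, 2L))
  expect_error(filter_clusters_by_topology(topo, c(holes = 1, voids = 0)),
               "without voids")
  # 3D tables additionally require the void count to match
  topo$table$voids_consensus <- c(0L, 1L, 0L, 0L)
  expect_equal(filter_clusters_by_topology(topo, c(holes = 1, voids = 0), 90),
               1L)
  expect_equal(filter_clusters_by_topology(topo, c(holes = 1), 89), 1L)
})

test_that("percent_correct classifies every error type on a worked example", {
  #          1  2  3  4  5  6  7  8  9 10
  true <- c(1L, 1L, 1L, 2L, 2L, 2L, 0L, 0L, 1L, 2L)
  pred <- c(5L, 5L, 5L, 9L, 9L, 0L, 9L, 0L, 9L, 5L)
  sc <- percent_correct(true, pred)
  # matching: true 1 -> pred 5, true 2 -> pred 9
  expect_equal(sc$matching, c(`1` = 5L, `2` = 9L))
  expect_equal(sc$n_correct, 6L)  # rows 1,2,3 + 4,5 + row 8 noise/noise
  expect_equal(sc$false_positive, 1L)        # row 7: noise in a cluster
  expect_equal(sc$false_negative, 1L)        # row 6: cluster member to noise
  expect_equal(sc$incorrect_assignment, 2L)  # rows 9, 10 swapped clusters
  expect_equal(sc$percent_correct, 60)
  expect_equal(sc$n, 10L)

  # perfect prediction up to label renaming scores 100
  expect_equal(percent_correct(true, c(7L, 7L, 7L, 3L, 3L, 3L, 0L, 0L, 7L, 3L)
                               )$percent_correct, 100)
  # all-noise prediction scores only the true noise
  expect_equal(percent_correct(true, rep(0L, 10))$percent_correct, 20)
  expect_error(percent_correct(true, pred[-1]), "equal length")
})

test_that("greedy matching equals exhaustive optimal matching on fixtures", {
  set.seed(51)
  for (rep in 1:12) {
    n <- sample(8:20, 1)
    true <- sample(0:3, n, replace = TRUE)
    pred <- true
    flip <- sample(n, ceiling(n / 3))
    pred[flip] <- sample(0:4, length(flip), replace = TRUE)
    expect_equal(percent_correct(true, pred)$percent_correct,
                 oracle_percent_correct(true, pred),
                 info = sprintf("fixture %d", rep))
  }
})

test_that("benchmark_clustering ranks algorithms on an easy planted scenario", {
  sc <- scenario_config("gaussian", field_size = c(1200, 1200), n_clusters = 3,
                        molecules_per_cluster = 15, cluster_sd = 10,
                        margin = 200)
  suite <- generate_benchmark_suite(list(easy = sc), reps = 2, seed = 17)
  grids <- list(tomato = parameter_grid("tomato", r = c(20, 30), tau = c(5, 15)),
                dbscan = parameter_grid("dbscan", eps = c(20, 30),
                                        min_pts = c(4, 10)))
  bm <- benchmark_clustering(suite, grids)
  expect_setequal(bm$best$algorithm, c("tomato", "dbscan"))
  expect_equal(nrow(bm$surface), 8L)
  expect_true(all(bm$best$percent_correct > 75))
  # the best row restates the winning parameters from the surface
  srow <- bm$surface[bm$surface$algorithm == "tomato", ]
  expect_equal(bm$best$percent_correct[bm$best$algorithm == "tomato"],
               max(srow$mean_percent_correct))
})
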