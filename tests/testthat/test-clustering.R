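make_blobs <- function(seed, k = 3, n = 35, sd = 6, sep = 70) {
  set.seed(seed)
  cen <- cbind(sep * (0:(k - 1)), sep * ((0:(k - 1)) %% 2))
  pts <- do.call(rbind, lapply(seq_len(k), function(i)
    cbind(rnorm(n, cen[i, 1], sd), rnorm(i * 0 + n, cen[i, 2], sd))))
  rbind(pts, cbind(runif(15, -50, sep * k), runif(15, -50, sep + 50)))
}

test_that("tomato_cluster matches an independent mode-merging implementation", {
  for (seed in c(1, 2, 3, 10)) {
    pts <- make_blobs(seed)
    for (r in c(8, 15, 25)) for (tau in c(0, 3, 8, 20)) {
      g <- build_radius_graph(pts, r)
      f <- radius_count_density(pts, r, graph = g)
      got <- tomato_cluster(pts, r, tau, graph = g, f = f)
      ref <- oracle_tomato(g$neighbors, as.numeric(f), tau)
      expect_identical(got$labels, ref)
    }
  }
})

test_that("tomato has the documented limiting and invariance behaviour", {
  pts <- make_blobs(4)
  g <- build_radius_graph(pts, 15)
  f <- radius_count_density(pts, 15, graph = g)

  # tau = 0: every density mode is its own cluster, nothing is noise
  cl0 <- tomato_cluster(pts, 15, 0)
  modes <- sum(vapply(seq_len(nrow(pts)), function(i)
    all(f[g$neighbors[[i]]] <= f[i]), TRUE))
  expect_equal(cl0$n_clusters, modes)
  expect_equal(sum(cl0$labels == 0), 0L)
  expect_equal(cl0$n_clusters, sum(!cl0$diagram$merged))

  # cluster count is non-increasing in tau
  taus <- c(0, 1, 2, 4, 8, 16, 32, 64)
  ks <- vapply(taus, function(tau) tomato_cluster(pts, 15, tau)$n_clusters, 0L)
  expect_true(all(diff(ks) <= 0))

  # tau beyond every density value: no candidate reaches the persistence bar
  cl_inf <- tomato_cluster(pts, 15, max(f) + 1)
  expect_equal(cl_inf$n_clusters, 0L)
  expect_true(all(cl_inf$labels == 0))

  # relabelling under point permutation: same partition, same noise set
  set.seed(99)
  perm <- sample(nrow(pts))
  cl <- tomato_cluster(pts, 15, 6)
  clp <- tomato_cluster(pts[perm, ], 15, 6)
  expect_equal(clp$labels == 0, (cl$labels == 0)[perm])
  agree <- outer(cl$labels[perm], cl$labels[perm], "==")
  agreep <- outer(clp$labels, clp$labels, "==")
  expect_true(all(agree == agreep))
})

test_that("the tomato diagram records births, deaths and merges coherently", {
  pts <- make_blobs(5)
  cl <- tomato_cluster(pts, 15, 6)
  d <- cl$diagram
  f <- radius_count_density(pts, 15)
  expect_equal(d$birth, f[d$mode])
  fin <- is.finite(d$death)
  expect_true(all(d$birth[fin] >= d$death[fin]))
  # exactly one -Inf death (component root) per graph component with a mode
  expect_true(all(d$death[!fin] == -Inf))
  expect_false(any(d$merged[!fin]))
  # a candidate's cluster column is the final label of its mode detection
  expect_equal(d$cluster, cl$labels[d$mode])
  # surviving candidates below the persistence bar are noise
  surv <- !d$merged
  pers <- d$birth - ifelse(is.finite(d$death), d$death, 0)
  expect_equal(d$cluster[surv] > 0, pers[surv] >= 6)
  expect_error(tomato_cluster(pts, -1, 5), "radius")
  expect_error(tomato_cluster(pts, 10, -2), "tau")
})

test_that("the density prefilter drops low-density detections to noise", {
  pts <- make_blobs(6)
  f <- radius_count_density(pts, 15)
  cl <- tomato_cluster(pts, 15, 6, prefilter_quantile = 0.2)
  cut <- quantile(f, 0.2)
  expect_true(all(cl$labels[f < cut] == 0))
})

test_that("dbscan_cluster matches a breadth-first reference", {
  for (seed in c(1, 5, 9)) {
    pts <- make_blobs(seed)
    for (eps in c(8, 14)) for (min_pts in c(3, 6, 12)) {
      g <- build_radius_graph(pts, eps)
      got <- dbscan_cluster(pts, eps, min_pts, graph = g)
      expect_identical(got$labels, oracle_dbscan(g$neighbors, min_pts))
    }
  }
  # a point whose neighbourhood (incl. itself) has exactly min_pts is core
  line <- cbind(c(0, 5, 10), c(0, 0, 0))
  expect_equal(dbscan_cluster(line, eps = 6, min_pts = 3)$labels,
               c(1L, 1L, 1L))
  expect_equal(dbscan_cluster(line, eps = 6, min_pts = 4)$labels,
               c(0L, 0L, 0L))
})

test_that("ripley and voronoi clustering find the planted blobs", {
  pts <- make_blobs(7)
  truth <- rep(c(1:3, 0L), times = c(35, 35, 35, 15))
  A <- prod(apply(pts, 2, function(v) diff(range(v))))

  rc <- ripley_cluster(pts, r = 20, score_threshold = 40, window_area = A)
  expect_gte(percent_correct(truth, rc)$percent_correct, 85)
  # raising the threshold only shrinks the clustered set
  rc2 <- ripley_cluster(pts, r = 20, score_threshold = 52, window_area = A)
  expect_true(all(rc$labels[rc2$labels > 0] > 0))

  vc <- voronoi_cluster(pts, max_tile_area = 150)
  expect_gte(percent_correct(truth, vc)$percent_correct, 80)
  # every kept tile is small and non-boundary by construction
  f <- voronoi_density(pts)
  expect_true(all(attr(f, "area")[vc$labels > 0] <= 150))
  expect_true(all(!attr(f, "boundary")[vc$labels > 0]))
})

test_that("parameter grids are exact Cartesian scans with checked names", {
  g <- parameter_grid("tomato")
  expect_equal(nrow(g), 50 * 51)
  expect_equal(sort(unique(g$r)), 1:50)
  expect_equal(sort(unique(g$tau)), 0:50)
  expect_equal(attr(g, "algorithm"), "tomato")

  gd <- parameter_grid("dbscan", eps = c(10, 20), min_pts = c(4, 8, 16))
  expect_equal(nrow(gd), 6L)
  expect_error(parameter_grid("dbscan", eps = 10, k = 4), "exactly")
  expect_error(parameter_grid("dbscan"), "required")
  expect_error(parameter_grid("voronoi", max_tile_area = numeric(0)), "empty")

  # run_clustering dispatches each algorithm with its grid-row parameters
  pts <- make_blobs(8)
  expect_identical(run_clustering(pts, "dbscan", gd[4, ])$labels,
                   dbscan_cluster(pts, gd$eps[4], gd$min_pts[4])$labels)
  expect_error(run_clustering(pts, "mystery", list()), "unknown algorithm")
})
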