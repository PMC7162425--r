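# Pure-R reference implementations used only by the tests. Each follows the
# mathematical definition directly and shares no code or data structures with
# the package internals; they are deliberately slow and simple.

# brute-force fixed-radius neighbour lists (inclusive boundary)
oracle_radius_graph <- function(coords, r) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  lapply(seq_len(n), function(i) which(D[i, ] <= r & seq_len(n) != i))
}

# full boundary-matrix GF(2) reduction of the Rips filtration; intended for
# n <= 12 points. Enumerates every simplex up to dimension max_dim with
# filtration value = max pairwise vertex distance, orders the simplices by
# (value, dimension, lexicographic vertex tuple) and reduces left to right.
oracle_rips <- function(coords, max_scale = NULL, max_dim = 2) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  if (is.null(max_scale)) max_scale <- if (n > 1) max(D) else 1
  simp <- list()
  filt <- numeric(0)
  dims <- integer(0)
  for (k in seq_len(min(max_dim + 1, n))) {
    for (vs in utils::combn(n, k, simplify = FALSE)) {
      fv <- if (k == 1) 0 else max(D[vs, vs])
      if (fv <= max_scale) {
        simp[[length(simp) + 1]] <- vs
        filt <- c(filt, fv)
        dims <- c(dims, k - 1L)
      }
    }
  }
  lexkey <- vapply(simp, function(v) paste(sprintf("%03d", v), collapse = ""), "")
  ord <- order(filt, dims, lexkey)
  simp <- simp[ord]; filt <- filt[ord]; dims <- dims[ord]
  m <- length(simp)
  index <- stats::setNames(seq_len(m), vapply(simp, paste, "", collapse = ","))
  cols <- vector("list", m)
  for (j in seq_len(m)) {
    if (dims[j] == 0) { cols[[j]] <- integer(0); next }
    faces <- lapply(seq_along(simp[[j]]), function(i) simp[[j]][-i])
    cols[[j]] <- sort(unname(index[vapply(faces, paste, "", collapse = ",")]))
  }
  pivot_of <- integer(m)         # pivot row -> reduced column
  killed <- logical(m)           # simplex used as a pivot row (its class dies)
  pairs <- NULL
  for (j in seq_len(m)) {
    col <- cols[[j]]
    while (length(col) && pivot_of[max(col)] != 0L) {
      other <- cols[[pivot_of[max(col)]]]
      col <- sort(c(setdiff(col, other), setdiff(other, col)))
    }
    cols[[j]] <- col
    if (length(col)) {
      i <- max(col)
      pivot_of[i] <- j
      killed[i] <- TRUE
      pairs <- rbind(pairs, c(dims[i], filt[i], filt[j]))
    }
  }
  for (j in seq_len(m)) {
    if (!length(cols[[j]]) && !killed[j] && dims[j] < max_dim)
      pairs <- rbind(pairs, c(dims[j], filt[j], Inf))
  }
  pd <- as.data.frame(pairs)
  names(pd) <- c("dimension", "birth", "death")
  pd <- pd[pd$death > pd$birth, , drop = FALSE]
  pd <- pd[order(pd$dimension, pd$birth, pd$death), , drop = FALSE]
  rownames(pd) <- NULL
  pd
}

# canonical comparable form of a persistence diagram
pd_canon <- function(pd) {
  out <- data.frame(dimension = as.integer(pd$dimension),
                    birth = round(pd$birth, 9), death = round(pd$death, 9))
  out <- out[order(out$dimension, out$birth, out$death), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# mode seeking with persistence merging on a neighbour graph, written from
# the documented contract (same tie conventions as tomato_cluster); returns
# per-detection labels
oracle_tomato <- function(nb, f, tau) {
  n <- length(f)
  ord <- order(-f, seq_len(n))
  rnk <- integer(n); rnk[ord] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  cand <- list()
  cand_of_root <- integer(n)
  for (i in ord) {
    higher <- nb[[i]][f[nb[[i]]] > f[i]]
    if (!length(higher)) {
      cand[[length(cand) + 1]] <- list(mode = i, birth = f[i],
                                       death = NA_real_, merged = FALSE)
      cand_of_root[i] <- length(cand)
    } else {
      parent[i] <- find(higher[order(-f[higher], higher)][1])
    }
    for (j in sort(nb[[i]][rnk[nb[[i]]] < rnk[i]])) {
      ri <- find(i); rj <- find(j)
      if (ri == rj) next
      ci <- cand_of_root[ri]; cj <- cand_of_root[rj]
      i_dies <- if (cand[[ci]]$birth != cand[[cj]]$birth)
        cand[[ci]]$birth < cand[[cj]]$birth else cand[[ci]]$mode > cand[[cj]]$mode
      clo <- if (i_dies) ci else cj; chi <- if (i_dies) cj else ci
      rlo <- if (i_dies) ri else rj; rhi <- if (i_dies) rj else ri
      if (is.na(cand[[clo]]$death)) cand[[clo]]$death <- f[i]
      if (cand[[clo]]$birth - f[i] < tau) {
        parent[rlo] <- rhi
        cand[[clo]]$merged <- TRUE
        cand_of_root[find(rhi)] <- chi
      }
    }
  }
  surv <- which(!vapply(cand, `[[`, TRUE, "merged"))
  surv <- surv[order(-vapply(cand[surv], `[[`, 0, "birth"),
                     vapply(cand[surv], `[[`, 0L, "mode"))]
  lab_of_cand <- integer(length(cand))
  nxt <- 0L
  for (c in surv) {
    death0 <- if (is.na(cand[[c]]$death)) 0 else cand[[c]]$death
    if (cand[[c]]$birth - death0 >= tau) { nxt <- nxt + 1L; lab_of_cand[c] <- nxt }
  }
  vapply(seq_len(n), function(i) lab_of_cand[cand_of_root[find(i)]], 0L)
}

# DBSCAN by breadth-first expansion from core points in index order
oracle_dbscan <- function(nb, min_pts) {
  n <- length(nb)
  core <- lengths(nb) + 1L >= min_pts
  labels <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    labels[i] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (j in nb[[v]]) if (labels[j] == 0L) {
        labels[j] <- nxt
        if (core[j]) queue <- c(queue, j)
      }
    }
  }
  labels
}

# percent correctly assigned under the best possible one-to-one matching of
# predicted to true clusters, by exhaustive search over injections
oracle_percent_correct <- function(true, pred) {
  true <- as.integer(true); pred <- as.integer(pred)
  tl <- sort(setdiff(unique(true), 0L))
  pl <- sort(setdiff(unique(pred), 0L))
  base <- sum(true == 0L & pred == 0L)
  recurse <- function(i, used) {
    if (i > length(tl)) return(0L)
    best <- recurse(i + 1L, used)
    for (p in setdiff(pl, used)) {
      ov <- sum(true == tl[i] & pred == p)
      best <- max(best, ov + recurse(i + 1L, c(used, p)))
    }
    best
  }
  matched <- if (length(tl)) recurse(1L, integer(0)) else 0L
  100 * (base + matched) / length(true)
}

# m evenly spaced points on a circle of radius R: the analytic Rips H1
# feature is (2 R sin(pi / m), 2 R sin(ceiling(m / 3) pi / m))
regular_polygon <- function(m, R = 10, centre = c(0, 0)) {
  ang <- 2 * pi * (seq_len(m) - 1) / m
  cbind(x = centre[1] + R * cos(ang), y = centre[2] + R * sin(ang))
}
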