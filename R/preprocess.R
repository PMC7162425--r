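#' Filter detections by photon count
#'
#' Keeps detections whose fitted intensity reaches `min_photons` (inclusive),
#' preserving row order. Dim fits carry large localization errors, so a
#' minimum photon count (1000 photons for the dye/camera combinations this
#' workflow was developed on) is the standard first cleaning step for real
#' dSTORM tables.
#'
#' @param t a [detection_table()] with an `intensity` column.
#' @param min_photons inclusive lower bound in photons.
#' @return The filtered `detection_table`.
#' @export
filter_by_intensity <- function(t, min_photons = 1000) {
  if (is.null(t$intensity))
    stop("configuration error: detection table has no intensity column")
  subset_detections(t, t$intensity >= min_photons)
}

#' Merge re-detections across consecutive frames
#'
#' A fluorophore that stays on for several camera frames is localized once
#' per frame. Detections found in strictly consecutive frames within
#' `max_dist` of the previous link are greedily chained (in frame order;
#' among several candidates in the next frame the nearest is linked, ties by
#' lower row index) and merged into a single detection: the merged position
#' is the intensity-weighted mean (unweighted when intensity is absent), the
#' merged intensity the sum, the merged frame the first frame of the chain
#' and the merged uncertainty the minimum over the chain.
#'
#' @param t a [detection_table()] with a `frame` column.
#' @param max_dist linking radius in nm (default 75).
#' @return A `detection_table` with merged detections; extra columns are
#'   dropped (they have no defined merge rule).
#' @export
link_consecutive_frames <- function(t, max_dist = 75) {
  if (max_dist <= 0) stop("parameter error: max_dist must be > 0")
  if (is.null(t$frame)) stop("configuration error: detection table has no frame column")
  n <- nrow(t)
  if (n == 0) return(t)
  coords <- det_coords(t)
  frames <- as.integer(t$frame)
  has_int <- !is.null(t$intensity)
  has_unc <- !is.null(t$uncertainty)

  chain_of <- integer(n)            # chain id per detection
  chain_last <- integer(0)          # detection index of each chain's tail
  next_chain <- 0L
  by_frame <- split(seq_len(n), frames)
  frame_vals <- as.integer(names(by_frame))
  ord <- order(frame_vals)
  by_frame <- by_frame[ord]
  frame_vals <- frame_vals[ord]

  active <- integer(0)              # chains whose tail is in the previous frame
  prev_frame <- NA_integer_
  for (fi in seq_along(frame_vals)) {
    f <- frame_vals[fi]
    dets <- by_frame[[fi]]
    if (!is.na(prev_frame) && f == prev_frame + 1L && length(active)) {
      claimed <- logical(length(dets))
      for (ch in active) {          # chains claim in id (row) order
        tail_i <- chain_last[ch]
        d2 <- colSums((base::t(coords[dets, , drop = FALSE]) - coords[tail_i, ])^2)
        d2[claimed] <- Inf
        k <- which.min(d2)          # nearest; ties -> lowest row index
        if (length(k) && is.finite(d2[k]) && d2[k] <= max_dist^2) {
          chain_of[dets[k]] <- ch
          chain_last[ch] <- dets[k]
          claimed[k] <- TRUE
        }
      }
      dets <- dets[!claimed]
    }
    for (i in dets) {               # unclaimed detections start new chains
      next_chain <- next_chain + 1L
      chain_of[i] <- next_chain
      chain_last[next_chain] <- i
    }
    active <- which(chain_last %in% by_frame[[fi]])
    active <- active[order(chain_last[active])]
    prev_frame <- f
  }

  nc <- next_chain
  idx <- split(seq_len(n), chain_of)
  idx <- idx[order(vapply(idx, min, integer(1)))]   # stable original order
  wsum <- function(v, w) sum(v * w) / sum(w)
  rows <- lapply(idx, function(ii) {
    w <- if (has_int) t$intensity[ii] else rep(1, length(ii))
    if (all(w == 0)) w <- rep(1, length(ii))
    pos <- apply(coords[ii, , drop = FALSE], 2, wsum, w = w)
    c(pos,
      frame = min(frames[ii]),
      intensity = if (has_int) sum(t$intensity[ii]) else NA_real_,
      uncertainty = if (has_unc) min(t$uncertainty[ii]) else NA_real_)
  })
  m <- do.call(rbind, rows)
  detection_table(x = m[, "x"], y = m[, "y"],
                  z = if ("z" %in% colnames(m)) m[, "z"] else NULL,
                  frame = as.integer(m[, "frame"]),
                  intensity = if (has_int) m[, "intensity"] else NULL,
                  uncertainty = if (has_unc) m[, "uncertainty"] else NULL)
}
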