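#' Detection tables
#'
#' A detection table is the basic data object of the package: one row per
#' localization (detection) from an SMLM/dSTORM experiment, holding the fitted
#' position in nanometres (2D or 3D), and optionally the acquisition frame,
#' the intensity in photons and the localization uncertainty (the estimated
#' standard deviation of the position error, in nm).
#'
#' Internally a detection table is a `data.frame` with columns `x`, `y`
#' (and `z` for 3D data), plus optional `frame`, `intensity` and
#' `uncertainty` columns and any extra columns carried through from file
#' import. Coordinates must be finite, frames non-negative integers and
#' uncertainties non-negative.
#'
#' @param x,y,z numeric coordinate vectors in nm (`z = NULL` for 2D data).
#' @param frame optional integer vector of acquisition frames (>= 0).
#' @param intensity optional numeric vector of photon counts.
#' @param uncertainty optional numeric vector of localization precisions (nm).
#' @param extra optional `data.frame` of additional per-detection columns.
#'
#' @return An object of class `detection_table` (a `data.frame`).
#' @examples
#' dt <- detection_table(x = c(0, 10, 20), y = c(0, 0, 0))
#' det_dim(dt)
#' @export
detection_table <- function(x, y, z = NULL, frame = NULL, intensity = NULL,
                            uncertainty = NULL, extra = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  df <- data.frame(x = as.numeric(x), y = as.numeric(y))
  if (!is.null(z)) {
    if (length(z) != n) stop("z must match x in length")
    df$z <- as.numeric(z)
  }
  if (!is.null(frame)) df$frame <- frame
  if (!is.null(intensity)) df$intensity <- as.numeric(intensity)
  if (!is.null(uncertainty)) df$uncertainty <- as.numeric(uncertainty)
  if (!is.null(extra)) {
    if (nrow(extra) != n) stop("extra columns must match the detection count")
    reserved <- intersect(names(extra), names(df))
    if (length(reserved)) stop("extra columns clash with reserved names: ",
                               paste(reserved, collapse = ", "))
    df <- cbind(df, extra)
  }
  class(df) <- c("detection_table", "data.frame")
  validate_detection_table(df)
}

#' @rdname detection_table
#' @param t a `detection_table`.
#' @export
validate_detection_table <- function(t) {
  if (!all(c("x", "y") %in% names(t))) stop("detection table needs x and y columns")
  coords <- det_coords(t)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!is.null(t$frame)) {
    fr <- t$frame
    if (any(!is.finite(fr)) || any(fr < 0) || any(fr != floor(fr)))
      stop("frame indices must be non-negative integers")
  }
  if (!is.null(t$uncertainty) && any(t$uncertainty < 0, na.rm = TRUE))
    stop("localization uncertainty must be >= 0")
  invisible(t)
}

#' @rdname detection_table
#' @export
det_dim <- function(t) if ("z" %in% names(t)) 3L else 2L

#' @rdname detection_table
#' @return `det_coords()` returns the n x dim coordinate matrix (nm).
#' @export
det_coords <- function(t) {
  cols <- if ("z" %in% names(t)) c("x", "y", "z") else c("x", "y")
  as.matrix(as.data.frame(t)[, cols, drop = FALSE])
}

#' @export
print.detection_table <- function(x, ...) {
  cat(sprintf("Detection table: %d detections, %dD\n", nrow(x), det_dim(x)))
  opt <- intersect(c("frame", "intensity", "uncertainty"), names(x))
  if (length(opt)) cat("  optional fields:", paste(opt, collapse = ", "), "\n")
  extras <- setdiff(names(x), c("x", "y", "z", "frame", "intensity", "uncertainty"))
  if (length(extras)) cat("  extra columns:", paste(extras, collapse = ", "), "\n")
  if (nrow(x)) {
    cat("\n")
    print(head(as.data.frame(x), 4))
    if (nrow(x) > 4) cat("  ...\n")
  }
  invisible(x)
}

# subset rows, keeping the class
subset_detections <- function(t, keep) {
  out <- as.data.frame(t)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("detection_table", "data.frame")
  out
}
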