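#' Column-mapping dialects for detection table files
#'
#' SMLM localization software writes delimited text tables with one header
#' row; a dialect maps the package's field names to the column headers of a
#' particular program. The default follows the ThunderSTORM CSV convention
#' (`"x [nm]"`, `"y [nm]"`, `"frame"`, `"intensity [photon]"`,
#' `"uncertainty [nm]"`). Any entry can be overridden, and entries set to
#' `NULL` are not looked for.
#'
#' @param x,y,z,frame,intensity,uncertainty column header names.
#' @return A named list usable as the `dialect` argument of
#'   [read_detections()] and [write_detections()].
#' @export
thunderstorm_dialect <- function(x = "x [nm]", y = "y [nm]", z = "z [nm]",
                                 frame = "frame", intensity = "intensity [photon]",
                                 uncertainty = "uncertainty [nm]") {
  list(x = x, y = y, z = z, frame = frame, intensity = intensity,
       uncertainty = uncertainty)
}

#' Read a detection table from delimited text
#'
#' Reads a ThunderSTORM-style delimited text file (comma separated by
#' default; tab accepted) with a header row, mapping columns to detection
#' fields through a dialect. Mapped columns must parse as numbers;
#' unmapped extra columns are kept verbatim and survive a round trip through
#' [write_detections()].
#'
#' @param path file path.
#' @param dialect column mapping, see [thunderstorm_dialect()]. `x` and `y`
#'   are required in the file; `z`, `frame`, `intensity` and `uncertainty`
#'   are used when present.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A [detection_table()].
#' @export
read_detections <- function(path, dialect = thunderstorm_dialect(), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("x", "y")
  for (f in need) {
    cn <- dialect[[f]]
    if (is.null(cn) || !cn %in% names(raw))
      stop(sprintf("format error: mapped column '%s' (field %s) not found",
                   if (is.null(cn)) "<unmapped>" else cn, f))
  }
  get_num <- function(field) {
    cn <- dialect[[field]]
    if (is.null(cn) || !cn %in% names(raw)) return(NULL)
    v <- raw[[cn]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "")
    if (length(bad))
      stop(sprintf("parse error in column '%s', row %d: non-numeric value '%s'",
                   cn, bad[1], as.character(v[bad[1]])))
    num
  }
  mapped <- vapply(dialect, function(cn) !is.null(cn) && cn %in% names(raw), logical(1))
  extra_cols <- setdiff(names(raw), unlist(dialect[mapped]))
  extra <- if (length(extra_cols)) raw[, extra_cols, drop = FALSE] else NULL
  detection_table(x = get_num("x"), y = get_num("y"), z = get_num("z"),
                  frame = get_num("frame"), intensity = get_num("intensity"),
                  uncertainty = get_num("uncertainty"), extra = extra)
}

#' Write a detection table to delimited text
#'
#' Writes headers according to the dialect; extra columns are appended
#' unchanged, and cluster labels (if given) are written as an additional
#' integer column.
#'
#' @param t a [detection_table()].
#' @param path output file path.
#' @param dialect column mapping, see [thunderstorm_dialect()].
#' @param labels optional integer cluster labels (0 = noise) appended as a
#'   `cluster` column.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_detections <- function(t, path, dialect = thunderstorm_dialect(),
                             labels = NULL, sep = ",") {
  out <- list()
  for (f in c("x", "y", "z", "frame", "intensity", "uncertainty")) {
    if (f %in% names(t) && !is.null(dialect[[f]])) {
      out[[dialect[[f]]]] <- t[[f]]
    }
  }
  extras <- setdiff(names(t), c("x", "y", "z", "frame", "intensity", "uncertainty"))
  for (e in extras) out[[e]] <- t[[e]]
  if (!is.null(labels)) {
    if (length(labels) != nrow(t)) stop("labels must match the detection count")
    out[["cluster"]] <- as.integer(labels)
  }
  df <- as.data.frame(out, check.names = FALSE, optional = TRUE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
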