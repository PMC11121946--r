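# Plain-text tilt-angle files (IMOD .tlt dialect: one decimal degree
# per line) and MRC-backed tilt-series round trips.

#' Read / write tilt angle files
#'
#' One angle in decimal degrees per line, ordered as acquired.
#'
#' @param path File path.
#' @param angles Numeric angles in degrees.
#' @return `read_angles` returns a numeric vector; `write_angles`
#'   returns `path` invisibly.
#' @export
read_angles <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("empty angle file: %s", path))
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("non-numeric angle at line %d of %s: '%s'",
                 bad, path, lines[bad]))
  }
  vals
}

#' @rdname read_angles
#' @export
write_angles <- function(angles, path) {
  writeLines(sprintf("%.4f", as.numeric(angles)), path)
  invisible(path)
}

#' Write / read a tilt series as an MRC stack plus angle file
#'
#' The image stack is stored as an MRC2014 file (x fastest, one section
#' per tilt) and the angles in a sibling `.tlt` file (same path with
#' the extension replaced, unless given).
#'
#' @param p A [tilt_series()].
#' @param path MRC file path.
#' @param angles_path Angle file path; default swaps the extension for
#'   `.tlt`.
#' @return `write_tilt_series` returns `path` invisibly;
#'   `read_tilt_series` returns a [tilt_series()].
#' @export
write_tilt_series <- function(p, path, angles_path = NULL) {
  stopifnot(inherits(p, "tilt_series"))
  if (is.null(angles_path)) angles_path <- sub("\\.[^.]*$", ".tlt", path)
  write_volume(volume(p$images), path)
  write_angles(p$geometry$angles, angles_path)
  invisible(path)
}

#' @rdname write_tilt_series
#' @export
read_tilt_series <- function(path, angles_path = NULL) {
  if (is.null(angles_path)) angles_path <- sub("\\.[^.]*$", ".tlt", path)
  v <- read_volume(path)
  tilt_series(v$data, tilt_geometry(angles = read_angles(angles_path)))
}
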