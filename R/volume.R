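#' Construct a density volume
#'
#' A `cryo_volume` is a 3D real-valued density grid with voxel dimensions
#' `(x, y, z)` and an optional physical voxel spacing.  It holds either a
#' ground-truth tomogram or a reconstruction estimate.
#'
#' @param data Numeric 3D array `(x, y, z)`.  All values must be finite.
#' @param voxel_size Physical spacing in Angstrom per voxel (default 1).
#'
#' @return An object of class `cryo_volume` with elements `data` (the
#'   array) and `voxel_size`.
#' @examples
#' v <- volume(array(0, c(8, 8, 4)))
#' dim(v)
#' @export
volume <- function(data, voxel_size = 1.0) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array (x, y, z)")
  }
  if (!all(is.finite(data))) {
    stop("volume contains non-finite values (NaN/Inf)")
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    stop("`voxel_size` must be a single positive number")
  }
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size)),
    class = "cryo_volume"
  )
}

#' @export
dim.cryo_volume <- function(x) dim(x$data)

#' @export
print.cryo_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<cryo_volume> %d x %d x %d voxels, %.3g A/voxel, range [%.4g, %.4g]\n",
    d[1], d[2], d[3], x$voxel_size, min(x$data), max(x$data)
  ))
  invisible(x)
}

is_volume <- function(x) inherits(x, "cryo_volume")

stopifnot_volume <- function(x, arg = deparse(substitute(x))) {
  if (!is_volume(x)) stop(sprintf("`%s` must be a cryo_volume", arg))
  invisible(x)
}

#' Crop a volume to a box
#'
#' Extracts an axis-aligned sub-box, e.g. to clip an external density map
#' to a cube before reconstruction experiments.
#'
#' @param v A [volume()].
#' @param x,y,z Integer index ranges (1-based, inclusive) along each axis.
#'   `NULL` keeps the full axis.
#' @return A [volume()] with the cropped grid.
#' @export
crop_volume <- function(v, x = NULL, y = NULL, z = NULL) {
  stopifnot_volume(v)
  d <- dim(v$data)
  rng <- function(r, n, axis) {
    if (is.null(r)) return(seq_len(n))
    r <- as.integer(r)
    if (min(r) < 1L || max(r) > n) {
      stop(sprintf("crop range out of bounds on %s-axis", axis))
    }
    seq.int(min(r), max(r))
  }
  volume(
    v$data[rng(x, d[1], "x"), rng(y, d[2], "y"), rng(z, d[3], "z"), drop = FALSE],
    voxel_size = v$voxel_size
  )
}

#' Affine-calibrate a volume against a reference
#'
#' Reconstructions produced from a normalized tilt series live on an
#' arbitrary linear intensity scale (the coordinate-network estimate in
#' normalized-projection units, the WBP estimate in filtered-sum
#' units).  This fits the least-squares gain and offset
#' `argmin ||a v + b - ref||^2` and applies them, so voxel-domain
#' metrics compare structure rather than the methods' arbitrary units.
#' The map is identical for every method and cannot raise a volume's
#' correlation with the reference.
#'
#' @param v A [volume()] to calibrate.
#' @param ref The reference [volume()].
#' @return A [volume()] on the reference scale.
#' @export
calibrate_volume <- function(v, ref) {
  stopifnot_volume(v); stopifnot_volume(ref)
  if (!identical(dim(v$data), dim(ref$data))) {
    stop("`v` and `ref` must have identical dimensions")
  }
  x <- as.numeric(v$data)
  y <- as.numeric(ref$data)
  vx <- stats::var(x)
  if (vx == 0) {
    v$data[] <- mean(y)
    return(v)
  }
  a <- stats::cov(x, y) / vx
  b <- mean(y) - a * mean(x)
  v$data <- a * v$data + b
  v
}

#' Rescale a volume linearly to the unit interval
#'
#' Min-max normalization, used to put reconstructions from different
#' methods on a common intensity scale before voxel-based metrics.
#' A constant volume maps to all zeros.
#'
#' @param v A [volume()].
#' @return A [volume()] spanning `[0, 1]`.
#' @export
normalize_volume <- function(v) {
  stopifnot_volume(v)
  r <- range(v$data)
  if (r[2] - r[1] <= 0) {
    v$data[] <- 0
    return(v)
  }
  v$data <- (v$data - r[1]) / (r[2] - r[1])
  v
}
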