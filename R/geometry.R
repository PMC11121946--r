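# Acquisition geometry and the parallel-beam projection operator.
#
# The projector follows the convention stated in cryocn-package.R: tilt
# axis = y, beam along +z at 0 degrees, positive angles rotating the
# beam toward +x.  Because every ray stays inside a single y-slice, the
# 3D operator factorizes into one 2D (x,z) -> x operator applied to each
# y-slice; that 2D operator is materialized once as a sparse matrix, so
# projection and its exact adjoint are single sparse-dense products.
# This decoupling along y is also what makes per-subvolume fitting exact
# rather than approximate.

#' Tilt-series acquisition geometry
#'
#' Either pass explicit `angles` (degrees, strictly increasing), or a
#' `step`/`range` pair generating `seq(-range, range, by = step)`.  The
#' default preset is the standard collection scheme: 2 degree steps over
#' \eqn{[-60, +60]}, i.e. 61 projections.
#'
#' @param angles Optional explicit tilt angles in degrees.
#' @param step Angular step \eqn{\alpha} in degrees (default 2).
#' @param range Half-range \eqn{\beta} in degrees (default 60); the
#'   series spans \eqn{[-\beta, +\beta]}.
#' @return A `tilt_geometry` with elements `angles`, `step`, `range`.
#' @examples
#' g <- tilt_geometry()
#' length(g$angles) # 61
#' @export
tilt_geometry <- function(angles = NULL, step = 2, range = 60) {
  if (is.null(angles)) {
    if (step <= 0 || range <= 0) stop("`step` and `range` must be positive")
    angles <- seq(-range, range, by = step)
  } else {
    step <- if (length(angles) > 1) stats::median(diff(angles)) else NA_real_
    range <- max(abs(angles))
  }
  angles <- as.numeric(angles)
  if (length(angles) < 1L) stop("geometry needs at least one tilt angle")
  if (any(diff(angles) <= 0)) stop("tilt angles must be strictly increasing")
  if (any(abs(angles) > 90)) {
    stop(sprintf("tilt angle %.2f outside [-90, 90]", angles[which.max(abs(angles))]))
  }
  structure(list(angles = angles, step = step, range = range),
            class = "tilt_geometry")
}

#' @export
print.tilt_geometry <- function(x, ...) {
  cat(sprintf("<tilt_geometry> %d angles in [%.1f, %.1f] deg (step %.3g)\n",
              length(x$angles), min(x$angles), max(x$angles), x$step))
  invisible(x)
}

#' Tilt series of projection images
#'
#' @param images Numeric 3D array `(x, y, l)`: `l` projection images of
#'   size `x` by `y`, one per tilt angle.
#' @param geometry A [tilt_geometry()] with `l` angles.
#' @return A `tilt_series` with elements `images` and `geometry`.
#' @export
tilt_series <- function(images, geometry) {
  if (!is.array(images) || length(dim(images)) != 3L) {
    stop("`images` must be a 3D array (x, y, l)")
  }
  if (!inherits(geometry, "tilt_geometry")) {
    stop("`geometry` must be a tilt_geometry")
  }
  if (dim(images)[3] != length(geometry$angles)) {
    stop(sprintf("image count %d does not match %d tilt angles",
                 dim(images)[3], length(geometry$angles)))
  }
  structure(list(images = images, geometry = geometry), class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<tilt_series> %d images of %d x %d, angles [%.1f, %.1f] deg\n",
              d[3], d[1], d[2], min(x$geometry$angles), max(x$geometry$angles)))
  invisible(x)
}

# ---------------------------------------------------------------------
# Sparse 2D projector: rays sampled at unit steps along the rotated beam
# direction with bilinear interpolation in the (x, z) plane; samples
# falling outside the grid contribute nothing.

.projector_cache <- new.env(parent = emptyenv())

#' Sparse parallel-beam projector matrix
#'
#' Builds the discrete projection operator for one `(x, z)` slice as a
#' sparse matrix of size `(l*x)` by `(x*z)`.  Row `ix + (a-1)*x` holds
#' the ray through detector pixel `ix` at angle `a`; column `ix + x*(iz)`
#' indexes voxel `(ix, iz)` (0-based, x fastest).  Rays are sampled at
#' unit steps with bilinear interpolation weights, so the matrix is both
#' the forward model and (transposed) its exact adjoint.
#'
#' @param x,z Slice dimensions in voxels.
#' @param angles Tilt angles in degrees, each with absolute value at
#'   most 90.
#' @return A `dgCMatrix`.
#' @export
projector_matrix <- function(x, z, angles) {
  if (any(abs(angles) > 90)) {
    stop(sprintf("cannot project at %.2f degrees: |angle| > 90",
                 angles[which.max(abs(angles))]))
  }
  key <- paste(x, z, paste(signif(angles, 10), collapse = ","), sep = "|")
  hit <- .projector_cache[[key]]
  if (!is.null(hit)) return(hit)
  cx <- (x - 1) / 2
  cz <- (z - 1) / 2
  Tmax <- ceiling(sqrt(x^2 + z^2) / 2)
  tt <- seq.int(-Tmax, Tmax)
  u0 <- seq_len(x) - 1 - cx
  ii <- jj <- ww <- vector("list", length(angles) * 4L)
  k <- 0L
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    px <- cx + outer(u0 * cos(th), tt * sin(th), "+")
    pz <- cz + outer(-u0 * sin(th), tt * cos(th), "+")
    x0 <- floor(px); fx <- px - x0
    z0 <- floor(pz); fz <- pz - z0
    rows <- matrix(seq_len(x) + (a - 1L) * x, nrow = x, ncol = length(tt))
    for (dx in 0:1) for (dz in 0:1) {
      xi <- x0 + dx; zi <- z0 + dz
      w <- (if (dx == 1) fx else 1 - fx) * (if (dz == 1) fz else 1 - fz)
      keep <- xi >= 0 & xi < x & zi >= 0 & zi < z & w > 0
      if (!any(keep)) next
      k <- k + 1L
      ii[[k]] <- rows[keep]
      jj[[k]] <- xi[keep] + 1L + x * zi[keep]
      ww[[k]] <- w[keep]
    }
  }
  A <- Matrix::sparseMatrix(
    i = unlist(ii[seq_len(k)]), j = unlist(jj[seq_len(k)]),
    x = unlist(ww[seq_len(k)]),
    dims = c(length(angles) * x, x * z)
  )
  # keep a small cache of recently used operators
  if (length(ls(.projector_cache)) > 8L) {
    rm(list = ls(.projector_cache)[1L], envir = .projector_cache)
  }
  .projector_cache[[key]] <- A
  A
}

# reshape (x, y, z) volume data to the (x*z) x y slice matrix the sparse
# operator acts on, and back
.vol_to_slices <- function(dat) {
  d <- dim(dat)
  matrix(aperm(dat, c(1, 3, 2)), d[1] * d[3], d[2])
}
.slices_to_vol <- function(m, x, y, z) {
  aperm(array(m, c(x, z, y)), c(1, 3, 2))
}

#' Project a volume into a tilt series
#'
#' Applies the parallel-beam operator \eqn{P}: for each tilt angle the
#' volume is integrated along the rotated beam direction at unit steps
#' (bilinear interpolation, zero outside the grid).  The operator is
#' linear in the volume, and `backproject()` applies its exact
#' transpose, so gradients of any loss on the projections propagate to
#' the volume — the property the coordinate-network fit relies on.
#'
#' At 0 degrees the projection equals the sum of the volume along z.
#'
#' @param v A [volume()].
#' @param g A [tilt_geometry()].
#' @return A [tilt_series()] of `l` images of size `x` by `y`.
#' @export
project <- function(v, g) {
  stopifnot_volume(v)
  d <- dim(v$data)
  A <- projector_matrix(d[1], d[3], g$angles)
  P2 <- as.matrix(A %*% .vol_to_slices(v$data))      # (l*x) x y
  l <- length(g$angles)
  images <- aperm(array(P2, c(d[1], l, d[2])), c(1, 3, 2))
  tilt_series(images, g)
}

#' Backproject a tilt series (adjoint of the projector)
#'
#' Applies the transpose of the discrete projection operator, smearing
#' each image back along its beam direction.  Satisfies the adjoint
#' identity `<P v, p> == <v, P^T p>` up to float roundoff.
#'
#' @param p A [tilt_series()].
#' @param z Number of z-voxels of the output volume (defaults to the
#'   image x-dimension, i.e. a cubic target).
#' @return A [volume()] of size `(x, y, z)`.
#' @export
backproject <- function(p, z = NULL) {
  stopifnot(inherits(p, "tilt_series"))
  d <- dim(p$images)
  if (is.null(z)) z <- d[1]
  A <- projector_matrix(d[1], z, p$geometry$angles)
  P2 <- matrix(aperm(p$images, c(1, 3, 2)), d[1] * d[3], d[2])
  V2 <- as.matrix(Matrix::crossprod(A, P2))          # (x*z) x y
  volume(.slices_to_vol(V2, d[1], d[2], z))
}

#' Normalize a tilt series to the unit interval
#'
#' One affine map is applied to the whole stack (global minimum to 0,
#' global maximum to 1), preserving relative intensities between tilt
#' images — per-image normalization would break the inter-tilt
#' consistency the reconstruction loss depends on.  A constant stack
#' maps to all zeros with a warning.
#'
#' @param p A [tilt_series()].
#' @return A normalized [tilt_series()]; the original `(min, max)` is
#'   attached as attribute `"norm_range"`.
#' @export
normalize_series <- function(p) {
  stopifnot(inherits(p, "tilt_series"))
  r <- range(p$images)
  if (r[2] - r[1] <= 0) {
    warning("constant tilt series: normalizing to all zeros")
    p$images[] <- 0
  } else {
    p$images <- (p$images - r[1]) / (r[2] - r[1])
  }
  attr(p, "norm_range") <- r
  p
}

#' Weighted back projection (WBP) baseline
#'
#' Minimal filtered-backprojection reconstruction: each projection image
#' is ramp-filtered along the tilt-perpendicular axis (x) in the Fourier
#' domain (no apodization), backprojected, and scaled by `1/l`.  With a
#' restricted tilt range the result shows the classic missing-wedge
#' elongation of objects along z.
#'
#' @param p A [tilt_series()].
#' @param z Output z-dimension (defaults to the image x-dimension).
#' @param filter `"ramp"` (default) or `"none"`.
#' @return A [volume()].
#' @export
wbp_reconstruct <- function(p, z = NULL, filter = c("ramp", "none")) {
  stopifnot(inherits(p, "tilt_series"))
  filter <- match.arg(filter)
  d <- dim(p$images)
  q <- p
  if (filter == "ramp") {
    ramp <- abs(.fftfreq(d[1]))
    for (a in seq_len(d[3])) {
      img <- matrix(p$images[, , a], d[1], d[2])
      F <- stats::mvfft(img)
      q$images[, , a] <- Re(stats::mvfft(F * ramp, inverse = TRUE)) / d[1]
    }
  }
  v <- backproject(q, z = z)
  v$data <- v$data / d[3]
  v
}
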