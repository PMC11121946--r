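# Phantom generators: binary slab volumes of hollow spheres or mixed
# geometric shapes, plus the preprocessing used before projection
# (Fourier low-pass smoothing, clamping of negative densities).

#' Phantom configuration
#'
#' Describes a synthetic ground-truth volume: a slab of binarized hollow
#' spheres (`kind = "spheres"`) or of mixed geometric shapes
#' (`kind = "shapes"`).  The default geometry is a thin slab (z smaller
#' than x and y), mimicking discrete objects suspended in a thin layer
#' of ice.
#'
#' @param kind `"spheres"` or `"shapes"`.
#' @param dims Integer `(x, y, z)` voxel counts.  Defaults to the
#'   full-scale slab `c(1024, 1024, 256)`.
#' @param n_objects Number of objects to place (default 32 for spheres,
#'   8 for shapes — one per shape class).
#' @param diameter_range `(min, max)` object diameter in voxels, drawn
#'   uniformly per object.  Default `c(16, 64)`.
#' @param shell_thickness Shell thickness in voxels for hollow spheres.
#'   `NULL` (default) uses 10% of each sphere's diameter, with a floor
#'   of 2 voxels.
#' @param seed Integer seed; a fixed seed makes the output bit-for-bit
#'   reproducible.
#' @param lowpass_cutoff Fraction of Nyquist used by [lowpass_filter()]
#'   when this phantom is smoothed (default 0.25).
#' @param overlap_allowed Logical; may objects overlap?  Defaults to
#'   `TRUE` for spheres and `FALSE` for shapes (so each placed shape
#'   remains a distinct connected component).
#'
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(kind = c("spheres", "shapes"),
                           dims = c(1024L, 1024L, 256L),
                           n_objects = NULL,
                           diameter_range = c(16, 64),
                           shell_thickness = NULL,
                           seed = 1L,
                           lowpass_cutoff = 0.25,
                           overlap_allowed = NULL) {
  kind <- match.arg(kind)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) {
    stop("`dims` must be three positive integers (x, y, z)")
  }
  if (is.null(n_objects)) n_objects <- if (kind == "spheres") 32L else 8L
  if (length(diameter_range) != 2L || any(diameter_range <= 0) ||
      diameter_range[1] > diameter_range[2]) {
    stop("`diameter_range` must be positive and ordered (min, max)")
  }
  if (diameter_range[2] > min(dims)) {
    stop(sprintf(
      "maximum diameter %g exceeds the smallest volume dimension %d",
      diameter_range[2], min(dims)
    ))
  }
  if (is.null(overlap_allowed)) overlap_allowed <- kind == "spheres"
  structure(
    list(
      kind = kind, dims = dims, n_objects = as.integer(n_objects),
      diameter_range = as.numeric(diameter_range),
      shell_thickness = shell_thickness, seed = as.integer(seed),
      lowpass_cutoff = lowpass_cutoff,
      overlap_allowed = isTRUE(overlap_allowed)
    ),
    class = "phantom_config"
  )
}

# Run expr with a private RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Rasterize a (hollow) sphere mask
#'
#' Voxels whose centers lie at Euclidean distance `d` from `center` with
#' `diameter/2 - thickness <= d <= diameter/2` are set to 1 (for
#' `thickness = NULL` or `>= diameter/2` the sphere is solid).  Centers
#' are in 0-based voxel units (voxel centers at integer coordinates).
#'
#' @param dims `(x, y, z)` voxel counts.
#' @param center Numeric length-3 center, 0-based voxel units.
#' @param diameter Sphere diameter in voxels.
#' @param thickness Shell thickness in voxels, or `NULL` for solid.
#' @return A binary `{0,1}` 3D array.
#' @export
sphere_shell_mask <- function(dims, center, diameter, thickness = NULL) {
  dims <- as.integer(dims)
  r_out <- diameter / 2
  r_in <- if (is.null(thickness)) -Inf else r_out - thickness
  # bounding box (1-based indices) around the sphere
  lo <- pmax(1L, floor(center - r_out) + 1L)
  hi <- pmin(dims, ceiling(center + r_out) + 1L)
  out <- array(0, dims)
  if (any(lo > hi)) return(out)
  dx2 <- (seq.int(lo[1], hi[1]) - 1 - center[1])^2
  dy2 <- (seq.int(lo[2], hi[2]) - 1 - center[2])^2
  dz2 <- (seq.int(lo[3], hi[3]) - 1 - center[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  d <- sqrt(d2)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    as.numeric(d <= r_out & d >= r_in)
  out
}

.default_shell <- function(diameter) max(2, 0.1 * diameter)

#' Generate a hollow-sphere phantom
#'
#' Places `n_objects` hollow spherical shells of unit density at uniform
#' random centers, with diameters drawn uniformly from
#' `diameter_range`.  Centers are rejection-sampled so every shell lies
#' fully inside the volume; overlap between spheres is permitted by
#' default.
#'
#' @param config A [phantom_config()] with `kind = "spheres"`.
#' @return A binary [volume()]; `$objects` is a tibble of placed objects
#'   (kind, center, diameter).
#' @export
generate_spheres <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$kind != "spheres") stop("config$kind must be 'spheres'")
  d <- config$dims
  dat <- array(0, d)
  objects <- vector("list", config$n_objects)
  with_seed(config$seed, {
    for (i in seq_len(config$n_objects)) {
      diam <- runif(1, config$diameter_range[1], config$diameter_range[2])
      if (diam > min(d) - 1) {
        # shells must fit fully inside (centers span [r, dim-1-r])
        stop(sprintf("sphere diameter %.1f does not fit inside dims %s",
                     diam, paste(d, collapse = "x")))
      }
      r <- diam / 2
      # uniform center such that the shell fits inside [0, dim-1]
      ctr <- vapply(d, function(n) runif(1, r, n - 1 - r), numeric(1))
      th <- if (is.null(config$shell_thickness)) .default_shell(diam)
            else config$shell_thickness
      # rasterize only inside the sphere's bounding box
      lo <- pmax(1L, floor(ctr - r) + 1L)
      hi <- pmin(d, ceiling(ctr + r) + 1L)
      dx2 <- (seq.int(lo[1], hi[1]) - 1 - ctr[1])^2
      dy2 <- (seq.int(lo[2], hi[2]) - 1 - ctr[2])^2
      dz2 <- (seq.int(lo[3], hi[3]) - 1 - ctr[3])^2
      dd <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
      blk <- dat[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      dat[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
        pmax(blk, as.numeric(dd <= r & dd >= r - th))
      objects[[i]] <- tibble::tibble(
        kind = "hollow_sphere", cx = ctr[1], cy = ctr[2], cz = ctr[3],
        size = diam
      )
    }
  })
  v <- volume(array(dat, d))
  v$objects <- if (config$n_objects > 0) do.call(rbind, objects) else
    tibble::tibble(kind = character(), cx = numeric(), cy = numeric(),
                   cz = numeric(), size = numeric())
  v
}

# --- shape rasterizers ------------------------------------------------
# Each returns a binary bounding-box mask for a shape of characteristic
# size s (its largest extent, in voxels).  Grids are 0-based voxel
# centers relative to the box center.

.shape_classes <- c("sphere", "ellipsoid", "pyramid", "cube", "prism",
                    "disc", "cross4", "cross6")

.shape_mask <- function(kind, s) {
  n <- max(3L, as.integer(ceiling(s)))
  if (n %% 2L == 0L) n <- n + 1L  # odd box so the center is a voxel
  g <- seq.int(0L, n - 1L) - (n - 1) / 2
  X <- array(rep(g, times = n * n), c(n, n, n))
  Y <- array(rep(rep(g, each = n), times = n), c(n, n, n))
  Z <- array(rep(g, each = n * n), c(n, n, n))
  h <- s / 2
  m <- switch(kind,
    sphere = X^2 + Y^2 + Z^2 <= h^2,
    ellipsoid = (X / h)^2 + (Y / (0.65 * h))^2 + (Z / (0.4 * h))^2 <= 1,
    pyramid = {
      # square base at z = -h, apex at z = +h
      t <- (Z + h) / s            # 0 at base, 1 at apex
      w <- pmax(0, (1 - t)) * h
      abs(X) <= w & abs(Y) <= w & t >= 0 & t <= 1
    },
    cube = {
      # exact box semantics: a side-s cube covers round(s)^3 voxels
      nc <- max(1L, as.integer(round(s)))
      return(array(1, c(nc, nc, nc)))
    },
    prism = {
      side <- pmax(1L, as.integer(round(s * c(1, 0.6, 0.35))))
      return(array(1, side))
    },
    disc = {
      th <- max(1, s / 8)
      X^2 + Y^2 <= h^2 & abs(Z) <= th / 2
    },
    cross4 = {
      w <- max(1, s / 8)
      (abs(X) <= h & abs(Y) <= w & abs(Z) <= w) |
        (abs(Y) <= h & abs(X) <= w & abs(Z) <= w)
    },
    cross6 = {
      w <- max(1, s / 8)
      (abs(X) <= h & abs(Y) <= w & abs(Z) <= w) |
        (abs(Y) <= h & abs(X) <= w & abs(Z) <= w) |
        (abs(Z) <= h & abs(X) <= w & abs(Y) <= w)
    },
    stop(sprintf("unknown shape class '%s'", kind))
  )
  m * 1
}

#' Generate a mixed-shape phantom
#'
#' Places binarized full spheres, ellipsoids, pyramids, cubes,
#' rectangular prisms, circular discs, and 4- and 6-pointed 3D crosses.
#' The first eight objects cover each shape class once; further objects
#' draw classes at random.  With `overlap_allowed = FALSE` (the default
#' for shapes) bounding boxes are rejection-sampled so placed shapes do
#' not touch.
#'
#' @param config A [phantom_config()] with `kind = "shapes"`.
#' @return A binary [volume()] with an `$objects` tibble.
#' @export
generate_shapes <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$kind != "shapes") stop("config$kind must be 'shapes'")
  d <- config$dims
  if (config$diameter_range[2] > min(d)) {
    stop(sprintf("largest shape size %g does not fit the smallest dimension %d",
                 config$diameter_range[2], min(d)))
  }
  dat <- array(0, d)
  placed <- list()
  with_seed(config$seed, {
    kinds <- c(
      .shape_classes[seq_len(min(config$n_objects, 8L))],
      if (config$n_objects > 8L) {
        sample(.shape_classes, config$n_objects - 8L, replace = TRUE)
      }
    )
    boxes <- list()
    for (i in seq_along(kinds)) {
      s <- runif(1, config$diameter_range[1], config$diameter_range[2])
      mask <- .shape_mask(kinds[i], s)
      nb <- dim(mask)
      if (any(nb > d)) stop("shape does not fit inside the volume")
      ok <- FALSE
      for (try in seq_len(200L)) {
        lo <- vapply(seq_len(3L), function(a) {
          sample.int(d[a] - nb[a] + 1L, 1L)
        }, integer(1))
        hi <- lo + nb - 1L
        if (!config$overlap_allowed && length(boxes) > 0) {
          clash <- any(vapply(boxes, function(b) {
            all(lo <= b$hi & hi >= b$lo)
          }, logical(1)))
          if (clash) next
        }
        ok <- TRUE
        break
      }
      if (!ok) {
        warning(sprintf("could not place object %d without overlap; skipped", i))
        next
      }
      boxes[[length(boxes) + 1L]] <- list(lo = lo, hi = hi)
      blk <- dat[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      dat[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- pmax(blk, mask)
      placed[[length(placed) + 1L]] <- tibble::tibble(
        kind = kinds[i],
        cx = mean(c(lo[1], hi[1])) - 1, cy = mean(c(lo[2], hi[2])) - 1,
        cz = mean(c(lo[3], hi[3])) - 1, size = s
      )
    }
  })
  v <- volume(array(dat, d))
  v$objects <- if (length(placed) > 0) do.call(rbind, placed) else
    tibble::tibble(kind = character(), cx = numeric(), cy = numeric(),
                   cz = numeric(), size = numeric())
  v
}

#' Generate a phantom from its configuration
#'
#' Dispatches on `config$kind`.
#' @param config A [phantom_config()].
#' @return A binary [volume()].
#' @export
generate_phantom <- function(config) {
  switch(config$kind,
    spheres = generate_spheres(config),
    shapes = generate_shapes(config)
  )
}

# centered frequency index / n, in cycles per voxel (Nyquist = 0.5)
.fftfreq <- function(n) {
  (((seq_len(n) - 1L) + floor(n / 2)) %% n - floor(n / 2)) / n
}

# |frequency| grid in cycles/voxel, laid out to match fft() output
.freq_radius <- function(dims) {
  fx <- .fftfreq(dims[1]); fy <- .fftfreq(dims[2]); fz <- .fftfreq(dims[3])
  sqrt(outer(outer(fx^2, fy^2, "+"), fz^2, "+"))
}

#' Low-pass filter a volume in Fourier space
#'
#' Smooths shape surfaces by attenuating Fourier amplitudes beyond a
#' cutoff expressed as a fraction of the Nyquist frequency.  The default
#' window is a Gaussian whose amplitude falls to 1/2 at the cutoff;
#' `window = "none"` applies no attenuation (identity, useful as a
#' control).
#'
#' @param v A [volume()].
#' @param cutoff Cutoff as a fraction of Nyquist, in `(0, 1]`.
#' @param window `"gaussian"` (default) or `"none"`.
#' @return A real-valued [volume()].
#' @export
lowpass_filter <- function(v, cutoff = 0.25, window = c("gaussian", "none")) {
  stopifnot_volume(v)
  window <- match.arg(window)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > 1) {
    stop("`cutoff` must be in (0, 1] (fraction of Nyquist)")
  }
  if (window == "none") return(v)
  d <- dim(v$data)
  fc <- 0.5 * cutoff                       # cycles/voxel
  sigma <- fc / sqrt(2 * log(2))           # half-amplitude at the cutoff
  H <- exp(-.freq_radius(d)^2 / (2 * sigma^2))
  out <- Re(fft(fft(v$data) * H, inverse = TRUE)) / prod(d)
  v$data <- out
  v
}

#' Clamp negative densities to zero
#'
#' @param v A [volume()].
#' @return A [volume()] with `max(value, 0)` applied elementwise.
#' @export
threshold_nonnegative <- function(v) {
  stopifnot_volume(v)
  v$data <- pmax(v$data, 0)
  v
}
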