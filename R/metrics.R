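# Reference-based evaluation of reconstructions: voxel-domain metrics
# (PSNR, SSIM, VIF), Fourier shell correlation, and the directional FSC
# restricted to the present / missing regions of Fourier space.
#
# Fourier conventions: frequencies are in cycles/voxel; a "Fourier
# voxel" is 1/n_ref cycles/voxel with n_ref = max(dims), so for cubic
# grids shell indices coincide with integer frequency indices and the
# Nyquist shell is n_ref/2.  Shells are unit width, a coefficient
# belonging to shell round(|k|).

.check_dims <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) {
    stop(sprintf("volume dimensions differ: %s vs %s",
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")))
  }
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(Im^2 / MSE)` in dB.  Identical volumes give `Inf`.
#'
#' @param vhat,vref Reconstruction and ground-truth [volume()]s of
#'   matching dimensions.
#' @param im Maximum possible value `Im`; defaults to `max(vref)`.
#' @return PSNR in dB.
#' @export
psnr <- function(vhat, vref, im = NULL) {
  stopifnot_volume(vhat); stopifnot_volume(vref)
  .check_dims(vhat, vref)
  if (is.null(im)) im <- max(vref$data)
  if (im <= 0) stop("`im` must be positive")
  mse <- mean((vhat$data - vref$data)^2)
  if (mse == 0) return(Inf)
  10 * log10(im^2 / mse)
}

# separable 'valid' convolution of a 3D array with a 1D kernel applied
# along all three axes (kernel assumed short relative to each dim)
.conv_valid3 <- function(arr, k) {
  len <- length(k)
  for (ax in 1:3) {
    d <- dim(arr)
    if (d[1] < len) stop("window larger than volume")
    m <- d[1] - len + 1L
    # band matrix: out[i] = sum_j k[j] * in[i + j - 1]
    Km <- matrix(0, m, d[1])
    for (jj in seq_len(len)) {
      Km[cbind(seq_len(m), seq_len(m) + jj - 1L)] <- k[jj]
    }
    arr <- array(Km %*% matrix(arr, d[1], d[2] * d[3]), c(m, d[2], d[3]))
    arr <- aperm(arr, c(2, 3, 1))
  }
  arr
}

.gauss_kernel <- function(len, sigma) {
  x <- seq_len(len) - (len + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Structural similarity index (3D)
#'
#' Mean local SSIM over 3D Gaussian windows (sigma 1.5 truncated at
#' 11^3 by default, K1 = 0.01, K2 = 0.03), with the dynamic range taken
#' from the ground truth.  Bounded in `[-1, 1]`; 1 iff the volumes are
#' identical.
#'
#' @param vhat,vref [volume()]s of matching dimensions.
#' @param sigma,window Gaussian window scale and truncation length.
#' @param K1,K2 Stability constants.
#' @param data_range Dynamic range; defaults to `diff(range(vref))`.
#' @return SSIM score.
#' @export
ssim <- function(vhat, vref, sigma = 1.5, window = 11L,
                 K1 = 0.01, K2 = 0.03, data_range = NULL) {
  stopifnot_volume(vhat); stopifnot_volume(vref)
  .check_dims(vhat, vref)
  if (any(dim(vref$data) < window)) stop("window larger than volume")
  if (is.null(data_range)) data_range <- diff(range(vref$data))
  if (data_range <= 0) data_range <- 1
  k <- .gauss_kernel(window, sigma)
  a <- vhat$data; b <- vref$data
  mu1 <- .conv_valid3(a, k); mu2 <- .conv_valid3(b, k)
  s11 <- .conv_valid3(a * a, k) - mu1^2
  s22 <- .conv_valid3(b * b, k) - mu2^2
  s12 <- .conv_valid3(a * b, k) - mu1 * mu2
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  m <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(m)
}

#' Visual information fidelity (pixel-domain, multiscale, 3D)
#'
#' Pixel-domain VIF under the Gaussian scale-mixture model, computed in
#' 3D over up to four dyadic scales (scales whose window no longer fits
#' the downsampled grid are dropped; the scales used are attached as an
#' attribute).  Equals 1 for identical volumes, falls in `(0, 1)` for
#' blurred reconstructions, and may exceed 1 for contrast enhancement.
#'
#' @param vhat,vref [volume()]s of matching dimensions; `vref` must not
#'   be constant.
#' @param sigma_nsq Visual noise variance (default 2).
#' @return VIF score with attribute `scales_used`.
#' @export
vif <- function(vhat, vref, sigma_nsq = 2) {
  stopifnot_volume(vhat); stopifnot_volume(vref)
  .check_dims(vhat, vref)
  if (stats::var(as.numeric(vref$data)) == 0) {
    stop("constant reference volume: VIF scene statistics are undefined")
  }
  ref <- vref$data; dist <- vhat$data
  eps <- 1e-10
  num <- 0; den <- 0; used <- integer(0)
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    k <- .gauss_kernel(N, N / 5)
    if (scale > 1) {
      if (any(dim(ref) < N)) break
      ref <- .conv_valid3(ref, k)
      dist <- .conv_valid3(dist, k)
      d <- dim(ref)
      ref <- ref[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2), drop = FALSE]
      dist <- dist[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2),
                   drop = FALSE]
    }
    if (any(dim(ref) < N)) break
    mu1 <- .conv_valid3(ref, k); mu2 <- .conv_valid3(dist, k)
    s1 <- pmax(.conv_valid3(ref * ref, k) - mu1^2, 0)
    s2 <- pmax(.conv_valid3(dist * dist, k) - mu2^2, 0)
    s12 <- .conv_valid3(ref * dist, k) - mu1 * mu2
    g <- s12 / (s1 + eps)
    sv <- s2 - g * s12
    g[s1 < eps] <- 0; sv[s1 < eps] <- s2[s1 < eps]; s1[s1 < eps] <- 0
    g[s2 < eps] <- 0; sv[s2 < eps] <- 0
    sv[g < 0] <- s2[g < 0]; g[g < 0] <- 0
    sv[sv <= eps] <- eps
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
    used <- c(used, scale)
  }
  if (den == 0) stop("reference volume carries no local variance for VIF")
  structure(num / den, scales_used = used)
}

# shared shell bookkeeping: returns integer shell index per Fourier
# coefficient plus the reference length defining a "Fourier voxel"
.shell_index <- function(dims) {
  nref <- max(dims)
  sh <- as.integer(round(.freq_radius(dims) * nref))
  list(shell = sh, nref = nref, nyquist = floor(nref / 2))
}

.fsc_core <- function(F1, F2, shell, nyquist, subset = NULL) {
  cross <- Re(F1 * Conj(F2))
  p1 <- Mod(F1)^2
  p2 <- Mod(F2)^2
  sv <- as.vector(shell)
  if (!is.null(subset)) {
    keepv <- as.vector(subset)
    sv <- sv[keepv]
    cross <- cross[keepv]; p1 <- p1[keepv]; p2 <- p2[keepv]
  }
  keep <- sv >= 1L & sv <= nyquist
  sv <- sv[keep]
  if (length(sv) == 0L) {
    return(tibble::tibble(shell = integer(), correlation = numeric(),
                          n_voxels = integer()))
  }
  agg <- rowsum(cbind(as.vector(cross)[keep], as.vector(p1)[keep],
                      as.vector(p2)[keep], 1), sv)
  shells <- as.integer(rownames(agg))
  denom <- sqrt(agg[, 2] * agg[, 3])
  ok <- denom > 0
  tibble::tibble(
    shell = shells[ok],
    correlation = (agg[ok, 1] / denom[ok]),
    n_voxels = as.integer(agg[ok, 4])
  )
}

#' Fourier shell correlation
#'
#' Per-shell normalized correlation of the two volumes' Fourier
#' transforms, computed without mean subtraction:
#' `Re(sum F1 conj(F2)) / sqrt(sum |F1|^2 sum |F2|^2)` over the
#' coefficients whose radius rounds to each shell, from shell 1 up to
#' Nyquist.  Scale-invariant in either argument; empty shells are
#' omitted.
#'
#' @param v1,v2 [volume()]s of matching dimensions.
#' @return An `fsc_curve`: tibble with `shell`, `correlation`,
#'   `n_voxels`.
#' @export
fsc <- function(v1, v2) {
  stopifnot_volume(v1); stopifnot_volume(v2)
  .check_dims(v1, v2)
  si <- .shell_index(dim(v1$data))
  F1 <- fft(v1$data); F2 <- fft(v2$data)
  out <- .fsc_core(F1, F2, si$shell, si$nyquist)
  class(out) <- c("fsc_curve", class(out))
  attr(out, "region") <- "full"
  out
}

#' Present / missing wedge masks in Fourier space
#'
#' A Fourier grid point `k` (in Fourier-voxel units) is "present" iff
#' its distance to some central section plane is at most `half_width`:
#' `min over angles of |k . n(theta)| <= half_width`, with beam
#' direction `n(theta) = (sin theta, 0, cos theta)`.  The "missing"
#' region is the complement.  Both masks are Hermitian-symmetric and
#' partition the grid.
#'
#' @param dims Volume dimensions `(x, y, z)`.
#' @param g A [tilt_geometry()].
#' @param half_width Slab half-width in Fourier voxels (default 0.5).
#' @return A `wedge_mask`: logical arrays `present` and `missing` in
#'   `fft()` layout, plus `geometry` and `half_width`.
#' @export
wedge_masks <- function(dims, g, half_width = 0.5) {
  dims <- as.integer(dims)
  stopifnot(inherits(g, "tilt_geometry"))
  nref <- max(dims)
  kx <- .fftfreq(dims[1]) * nref
  kz <- .fftfreq(dims[3]) * nref
  th <- g$angles * pi / 180
  # distance to the nearest section plane depends only on (kx, kz)
  dmin <- matrix(Inf, dims[1], dims[3])
  for (t in th) {
    dmin <- pmin(dmin, abs(outer(kx * sin(t), kz * cos(t), "+")))
  }
  present2d <- dmin <= half_width
  present <- aperm(
    array(rep(present2d, times = dims[2]), c(dims[1], dims[3], dims[2])),
    c(1, 3, 2)
  )
  structure(
    list(present = present, missing = !present,
         geometry = g, half_width = half_width, dims = dims),
    class = "wedge_mask"
  )
}

#' Directional Fourier shell correlation
#'
#' The [fsc()] computation restricted, within each shell, to the
#' Fourier grid points of the chosen wedge region.  The missing-region
#' curve isolates how much of the never-measured wedge a reconstruction
#' method has restored; shells containing no region voxels are omitted.
#'
#' @param v1,v2 [volume()]s of matching dimensions.
#' @param masks A [wedge_masks()] object built on the same dimensions.
#' @param region `"present"` or `"missing"`.
#' @return An `fsc_curve` with attribute `region`.
#' @export
directional_fsc <- function(v1, v2, masks, region = c("present", "missing")) {
  stopifnot_volume(v1); stopifnot_volume(v2)
  region <- match.arg(region)
  stopifnot(inherits(masks, "wedge_mask"))
  .check_dims(v1, v2)
  if (!identical(dim(v1$data), dim(masks$present))) {
    stop("wedge masks were built for different dimensions")
  }
  si <- .shell_index(dim(v1$data))
  F1 <- fft(v1$data); F2 <- fft(v2$data)
  out <- .fsc_core(F1, F2, si$shell, si$nyquist, subset = masks[[region]])
  if (nrow(out) == 0L) warning(sprintf("empty %s region at all shells", region))
  class(out) <- c("fsc_curve", class(out))
  attr(out, "region") <- region
  out
}

#' Full metrics report for a reconstruction
#'
#' Computes PSNR, 3D SSIM, 3D multiscale VIF, the whole-volume FSC, and
#' the present- and missing-region directional FSC against a ground
#' truth.
#'
#' @param vhat,vref Reconstruction and reference [volume()]s.
#' @param g A [tilt_geometry()] (defines the wedge masks).
#' @param im `Im` for PSNR; defaults to `max(vref)`.
#' @param half_width Wedge-slab half-width in Fourier voxels.
#' @return A `metrics_report` list.
#' @export
evaluate_volumes <- function(vhat, vref, g, im = NULL, half_width = 0.5) {
  stopifnot_volume(vhat); stopifnot_volume(vref)
  .check_dims(vhat, vref)
  masks <- wedge_masks(dim(vref$data), g, half_width)
  if (is.null(im)) im <- max(vref$data)
  # window-based metrics are undefined on volumes smaller than their
  # windows; report NA rather than refusing the whole report
  soft <- function(expr) tryCatch(expr, error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    NA_real_
  })
  structure(
    list(
      psnr = psnr(vhat, vref, im = im),
      ssim = soft(ssim(vhat, vref)),
      vif = soft(vif(vhat, vref)),
      fsc_full = fsc(vhat, vref),
      fsc_present = directional_fsc(vhat, vref, masks, "present"),
      fsc_missing = directional_fsc(vhat, vref, masks, "missing"),
      im = im,
      notes = c(ssim_domain = "3D", vif_variant = "pixel-domain multiscale")
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  fsc_mean <- function(cv) if (nrow(cv)) mean(cv$correlation) else NA_real_
  cat(sprintf(
    paste0("<metrics_report> PSNR %.2f dB | SSIM %.4f | VIF %.4f\n",
           "  mean FSC: full %.3f, present %.3f, missing %.3f\n"),
    x$psnr, x$ssim, as.numeric(x$vif),
    fsc_mean(x$fsc_full), fsc_mean(x$fsc_present), fsc_mean(x$fsc_missing)
  ))
  invisible(x)
}

#' One-row tibble of a metrics report's scalar values
#'
#' @param report A [evaluate_volumes()] result.
#' @return A tibble with PSNR, SSIM, VIF and mean FSC columns.
#' @export
report_summary <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  fsc_mean <- function(cv) if (nrow(cv)) mean(cv$correlation) else NA_real_
  tibble::tibble(
    psnr = report$psnr, ssim = report$ssim, vif = as.numeric(report$vif),
    fsc_full_mean = fsc_mean(report$fsc_full),
    fsc_present_mean = fsc_mean(report$fsc_present),
    fsc_missing_mean = fsc_mean(report$fsc_missing)
  )
}

# 6-connected component labelling on a logical 3D mask (vectorized
# frontier expansion; adequate for desk-scale segmentations)
.label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  n <- prod(d)
  strides <- c(1L, d[1], d[1] * d[2])
  todo <- which(mask)
  cur <- 0L
  for (seed in todo) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier)) {
      nxt <- integer(0)
      i0 <- frontier - 1L
      ix <- i0 %% d[1]
      iy <- (i0 %/% d[1]) %% d[2]
      iz <- i0 %/% (d[1] * d[2])
      pos <- list(ix, iy, iz)
      for (ax in 1:3) {
        for (s in c(-1L, 1L)) {
          ok <- if (s < 0) pos[[ax]] > 0L else pos[[ax]] < d[ax] - 1L
          nb <- frontier[ok] + s * strides[ax]
          nb <- nb[mask[nb] & lab[nb] == 0L]
          if (length(nb)) {
            lab[nb] <- cur
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' z-elongation anisotropy of segmented objects
#'
#' Binarizes the volume at `threshold_frac * max(v)`, labels
#' 6-connected components, and returns the size-weighted mean of each
#' component's z-extent over x-extent.  An isotropic object scores ~1;
#' missing-wedge streaking along z inflates the score.
#'
#' @param v A [volume()].
#' @param threshold_frac Threshold as a fraction of the maximum
#'   (default 0.5).
#' @param min_voxels Ignore components smaller than this (default 20).
#' @return Anisotropy statistic (dimensionless).
#' @export
elongation_anisotropy <- function(v, threshold_frac = 0.5, min_voxels = 20L) {
  stopifnot_volume(v)
  mask <- v$data >= threshold_frac * max(v$data)
  lab <- .label_components(mask)
  ncomp <- max(lab)
  if (ncomp == 0L) return(NA_real_)
  d <- dim(mask)
  idx <- which(lab > 0L)
  i0 <- idx - 1L
  comp <- lab[idx]
  ix <- i0 %% d[1]
  iz <- i0 %/% (d[1] * d[2])
  ratios <- sizes <- numeric(0)
  for (cc in seq_len(ncomp)) {
    sel <- comp == cc
    if (sum(sel) < min_voxels) next
    xr <- diff(range(ix[sel])) + 1L
    zr <- diff(range(iz[sel])) + 1L
    ratios <- c(ratios, zr / xr)
    sizes <- c(sizes, sum(sel))
  }
  if (length(ratios) == 0L) return(NA_real_)
  sum(ratios * sizes) / sum(sizes)
}

#' Plot FSC curves
#'
#' Draws one or more FSC curves (full or directional) on a common
#' shell axis.
#'
#' @param ... Named `fsc_curve` objects; names become the legend.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_fsc <- function(...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  curves <- list(...)
  nms <- names(curves)
  if (is.null(nms) || any(nms == "")) {
    nms <- paste0("curve", seq_along(curves))
  }
  df <- do.call(rbind, Map(function(cv, nm) {
    tibble::tibble(shell = cv$shell, correlation = cv$correlation, curve = nm)
  }, curves, nms))
  ggplot2::ggplot(df, ggplot2::aes(x = shell, y = correlation,
                                   colour = curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "Fourier shell (voxels)", y = "correlation")
}

utils::globalVariables(c("shell", "correlation", "curve"))

`%||%` <- function(a, b) if (is.null(a)) b else a
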