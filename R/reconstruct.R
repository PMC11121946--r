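# Unsupervised reconstruction: partition the tilt series into y-axis
# subslices, fit one coordinate network per subvolume against its own
# projections (warm-starting each network from its neighbour), and
# stitch the evaluated subvolumes back together.

#' Optimization settings for subvolume fitting
#'
#' Defaults follow the standard protocol: 2000 Adam iterations for the
#' first (cold-started) subvolume with the learning rate decayed
#' logarithmically from 1e-3 to 1e-4, and 400 iterations from 1e-4 to
#' 1e-5 for every adjacent subvolume that starts from its neighbour's
#' fitted weights.  The data term is the mean squared reprojection
#' error; `lambda = 0` disables the regularizer by default.
#'
#' @param iterations_first,iterations_adjacent Iteration counts
#'   (defaults 2000 and 400).
#' @param lr_first,lr_adjacent `(start, end)` learning-rate pairs
#'   (defaults `c(1e-3, 1e-4)` and `c(1e-4, 1e-5)`).
#' @param lambda Regularization strength (>= 0, default 0).
#' @param regularizer `"none"` or `"total_variation"` (smoothed
#'   anisotropic TV, mean per voxel pair).
#' @param seed Integer seed controlling initialization and coordinate
#'   batching.
#' @param adam_beta Adam moment constants `(beta1, beta2)`.  The default
#'   `c(0.9, 0.99)` uses a faster-adapting second moment than the
#'   generic 0.999, which suits the short, aggressively decayed
#'   schedules used here.
#' @param coords_per_step `"all"` (default) evaluates the full
#'   subvolume grid each step; a number requests stochastic batches of
#'   approximately that many coordinates, rounded to whole y-slices so
#'   each batch's projection loss stays exact.
#' @return A `fit_config`.
#' @export
fit_config <- function(iterations_first = 2000L, iterations_adjacent = 400L,
                       lr_first = c(1e-3, 1e-4),
                       lr_adjacent = c(1e-4, 1e-5),
                       lambda = 0, regularizer = c("none", "total_variation"),
                       seed = 0L, coords_per_step = "all",
                       adam_beta = c(0.9, 0.99)) {
  regularizer <- match.arg(regularizer)
  if (lambda < 0) stop("`lambda` must be >= 0")
  if (iterations_first < 1L || iterations_adjacent < 1L) {
    stop("iteration counts must be >= 1")
  }
  chk_lr <- function(lr, nm) {
    if (length(lr) != 2L || any(lr <= 0) || lr[1] < lr[2]) {
      stop(sprintf("`%s` must be positive with start >= end", nm))
    }
  }
  chk_lr(lr_first, "lr_first")
  chk_lr(lr_adjacent, "lr_adjacent")
  if (!identical(coords_per_step, "all") &&
      (!is.numeric(coords_per_step) || coords_per_step < 1)) {
    stop("`coords_per_step` must be \"all\" or a positive count")
  }
  if (length(adam_beta) != 2L || any(adam_beta <= 0) || any(adam_beta >= 1)) {
    stop("`adam_beta` must be two values in (0, 1)")
  }
  structure(
    list(iterations_first = as.integer(iterations_first),
         iterations_adjacent = as.integer(iterations_adjacent),
         lr_first = as.numeric(lr_first), lr_adjacent = as.numeric(lr_adjacent),
         lambda = as.numeric(lambda), regularizer = regularizer,
         seed = as.integer(seed), coords_per_step = coords_per_step,
         adam_beta = as.numeric(adam_beta)),
    class = "fit_config"
  )
}

#' Plan the y-axis subvolume partition
#'
#' Chooses the subslice width `j` as the largest power of two for which
#' the nominal parameter count still provides at least `target_ratio`
#' parameters per subvolume voxel, i.e.
#' `nominal_param_count(spec) / (x * j * z) >= target_ratio`, clamped to
#' `[1, y]`.  The y-axis is tiled with `ceiling(y / j)` half-open
#' intervals; only the last may be narrower.
#'
#' @param dims Integer `(x, y, z)` of the full volume.
#' @param spec A [network_spec()].
#' @param target_ratio Nominal parameters per subvolume voxel
#'   (default 1/8).
#' @return A `subvolume_plan` with `width`, `n_subvolumes` and an
#'   `intervals` tibble (0-based half-open `y_start`/`y_end`).
#' @examples
#' plan_subvolumes(c(1024, 1024, 256), network_spec(4, 256))$n_subvolumes # 128
#' @export
plan_subvolumes <- function(dims, spec, target_ratio = 1 / 8) {
  dims <- as.integer(dims)
  stopifnot(inherits(spec, "network_spec"))
  if (target_ratio <= 0) stop("`target_ratio` must be positive")
  if (length(dims) != 3L || any(dims < 1L)) stop("`dims` must be positive")
  bound <- nominal_param_count(spec) / (target_ratio * dims[1] * dims[3])
  j <- if (bound >= 1) 2^floor(log2(bound)) else 1
  j <- as.integer(max(1L, min(j, dims[2])))
  n <- as.integer(ceiling(dims[2] / j))
  y_start <- (seq_len(n) - 1L) * j
  y_end <- pmin(y_start + j, dims[2])
  structure(
    list(
      width = j, n_subvolumes = n, dims = dims,
      target_ratio = target_ratio,
      intervals = tibble::tibble(
        index = seq_len(n), y_start = y_start, y_end = y_end,
        width = as.integer(y_end - y_start)
      )
    ),
    class = "subvolume_plan"
  )
}

#' @export
print.subvolume_plan <- function(x, ...) {
  cat(sprintf(
    "<subvolume_plan> %d subvolume(s) of width %d over y = %d (dims %s)\n",
    x$n_subvolumes, x$width, x$dims[2], paste(x$dims, collapse = "x")
  ))
  invisible(x)
}

#' Extract the tilt-series slice for one subvolume
#'
#' Returns the projections restricted to the plan's i-th y-interval.
#' Because the tilt axis is y, these are exactly the measurements of the
#' i-th subvolume; concatenating all slices restores the series
#' bit-exactly.
#'
#' @param p A [tilt_series()].
#' @param plan A [plan_subvolumes()] result.
#' @param index Subvolume index in `1..n_subvolumes`.
#' @return A [tilt_series()] with images of width `plan$intervals$width[index]`.
#' @export
slice_series <- function(p, plan, index) {
  stopifnot(inherits(p, "tilt_series"), inherits(plan, "subvolume_plan"))
  if (index < 1L || index > plan$n_subvolumes) {
    stop(sprintf("subvolume index %d out of range 1..%d",
                 index, plan$n_subvolumes))
  }
  iv <- plan$intervals[index, ]
  tilt_series(p$images[, (iv$y_start + 1L):iv$y_end, , drop = FALSE],
              p$geometry)
}

#' Logarithmically decayed learning rate
#'
#' `lr(step) = lr_start * (lr_end / lr_start)^(step / (total_steps - 1))`
#' with 0-based `step`; monotone decreasing from `lr_start` to `lr_end`.
#' With fewer than two total steps the start rate is returned.
#'
#' @param step 0-based step index (vectorized).
#' @param total_steps Total number of steps.
#' @param lr_start,lr_end Endpoint learning rates.
#' @return Learning rate(s).
#' @export
lr_schedule <- function(step, total_steps, lr_start, lr_end) {
  if (any(step < 0) || any(step >= total_steps)) {
    stop("`step` must satisfy 0 <= step < total_steps")
  }
  if (total_steps < 2L) return(rep(lr_start, length(step)))
  lr_start * (lr_end / lr_start)^(step / (total_steps - 1))
}

.batch_slices <- function(coords_per_step, x, z, j) {
  if (identical(coords_per_step, "all")) return(0L)
  max(1L, min(j, as.integer(round(coords_per_step / (x * z)))))
}

#' Fit a coordinate network to one subvolume's projections
#'
#' Minimizes the mean squared error between the network's reprojections
#' and the measured tilt images (plus `lambda` times the regularizer)
#' by Adam with a log-decayed learning rate.  A cold start draws fresh
#' sine-layer initialization from the config seed and runs
#' `iterations_first` steps; passing `init` (the neighbouring
#' subvolume's fitted weights) switches to the adjacent protocol:
#' `iterations_adjacent` steps at the lower learning rates.
#'
#' @param p_sub A [tilt_series()] slice, normalized to `[0, 1]`.
#' @param z Number of z-voxels of the subvolume.
#' @param spec A [network_spec()].
#' @param fit A [fit_config()].
#' @param init Optional `network_params` warm start.
#' @return A `cn_fit`: `params`, `loss_trace`, `iterations`, `warm`,
#'   and `final_loss`.
#' @export
fit_subvolume <- function(p_sub, z, spec = network_spec(),
                          fit = fit_config(), init = NULL) {
  stopifnot(inherits(p_sub, "tilt_series"))
  d <- dim(p_sub$images)
  x <- d[1]; j <- d[2]; l <- d[3]
  r <- range(p_sub$images)
  if (r[1] < -1e-6 || r[2] > 1 + 1e-6) {
    warning("tilt series is not normalized to [0, 1]; see normalize_series()")
  }
  warm <- !is.null(init)
  params <- if (warm) init else init_params(spec, fit$seed)
  if (!identical(params$spec$features, spec$features) ||
      !identical(params$spec$hidden_layers, spec$hidden_layers)) {
    stop("`init` architecture does not match `spec`")
  }
  iterations <- if (warm) fit$iterations_adjacent else fit$iterations_first
  lr <- if (warm) fit$lr_adjacent else fit$lr_first
  A <- projector_matrix(x, z, p_sub$geometry$angles)
  enc <- .encode_set(make_grid(c(x, j, z)), spec)
  target <- matrix(aperm(p_sub$images, c(1, 3, 2)), x * l, j)
  res <- .fit_core(
    params$W, params$b, enc, x, j, z,
    A@p, A@i, A@x, nrow(A), target,
    as.integer(iterations), lr[1], lr[2], spec$omega0,
    fit$lambda, fit$regularizer == "total_variation",
    .batch_slices(fit$coords_per_step, x, z, j),
    fit$seed + 7L, fit$adam_beta[1], fit$adam_beta[2]
  )
  out <- structure(
    list(
      params = structure(
        list(W = res$W, b = lapply(res$b, as.numeric),
             spec = spec, seed = params$seed),
        class = "network_params"
      ),
      loss_trace = as.numeric(res$loss),
      iterations = as.integer(iterations),
      warm = warm,
      final_loss = tail(as.numeric(res$loss), 1L)
    ),
    class = "cn_fit"
  )
  out
}

#' @export
print.cn_fit <- function(x, ...) {
  cat(sprintf("<cn_fit> %d iterations (%s start), loss %.3e -> %.3e\n",
              x$iterations, if (x$warm) "warm" else "cold",
              x$loss_trace[1], x$final_loss))
  invisible(x)
}

#' Reconstruct a volume from a tilt series with coordinate networks
#'
#' Plans the y-axis partition, fits the subvolumes in order — the first
#' from scratch, each later one initialized from its predecessor's
#' fitted weights (learned initialization) — evaluates each network on
#' its voxel grid, and concatenates the subvolumes along y.
#'
#' @param p A normalized [tilt_series()].
#' @param z Number of z-voxels of the reconstruction.
#' @param spec A [network_spec()].
#' @param fit A [fit_config()].
#' @param target_ratio Nominal parameters per subvolume voxel for the
#'   planner (default 1/8).
#' @param plan Optional precomputed [plan_subvolumes()] result.
#' @return A `cn_reconstruction`: `volume` (the estimate), `report`
#'   (per-subvolume tibble), `plan`, `spec`, `fit`, and `fits` (the
#'   per-subvolume `cn_fit` objects).
#' @export
reconstruct_volume <- function(p, z, spec = network_spec(),
                               fit = fit_config(), target_ratio = 1 / 8,
                               plan = NULL) {
  stopifnot(inherits(p, "tilt_series"))
  d <- dim(p$images)
  dims <- c(d[1], d[2], as.integer(z))
  if (is.null(plan)) plan <- plan_subvolumes(dims, spec, target_ratio)
  blocks <- vector("list", plan$n_subvolumes)
  fits <- vector("list", plan$n_subvolumes)
  rows <- vector("list", plan$n_subvolumes)
  prev <- NULL
  for (i in seq_len(plan$n_subvolumes)) {
    t0 <- proc.time()[["elapsed"]]
    p_sub <- slice_series(p, plan, i)
    f <- tryCatch(
      fit_subvolume(p_sub, z, spec = spec, fit = fit, init = prev),
      error = function(e) {
        stop(sprintf("subvolume %d failed: %s", i, conditionMessage(e)))
      }
    )
    w <- plan$intervals$width[i]
    blocks[[i]] <- array(
      evaluate_network(f$params, make_grid(c(dims[1], w, dims[3]))),
      c(dims[1], w, dims[3])
    )
    prev <- f$params
    fits[[i]] <- f
    rows[[i]] <- tibble::tibble(
      subvolume = i, y_start = plan$intervals$y_start[i], width = w,
      iterations = f$iterations, warm = f$warm,
      loss_initial = f$loss_trace[1], loss_final = f$final_loss,
      seconds = proc.time()[["elapsed"]] - t0
    )
  }
  # stitch: hard concatenation along y (no blending)
  est <- array(0, dims)
  for (i in seq_len(plan$n_subvolumes)) {
    iv <- plan$intervals[i, ]
    est[, (iv$y_start + 1L):iv$y_end, ] <- blocks[[i]]
  }
  structure(
    list(volume = volume(est), report = do.call(rbind, rows),
         plan = plan, spec = spec, fit = fit, fits = fits),
    class = "cn_reconstruction"
  )
}

#' @export
print.cn_reconstruction <- function(x, ...) {
  cat(sprintf(
    "<cn_reconstruction> %s volume from %d subvolume(s); final losses %s\n",
    paste(dim(x$volume$data), collapse = "x"), x$plan$n_subvolumes,
    paste(sprintf("%.2e", x$report$loss_final), collapse = ", ")
  ))
  invisible(x)
}
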