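# End-to-end experiment driver: simulate -> project -> normalize ->
# {coordinate-network reconstruction, WBP} -> evaluate, optionally swept
# over acquisition parameters alpha (angular step) and beta (angular
# range).

#' Experiment configuration
#'
#' Bundles everything a run needs; with the global `seed` it is a
#' complete reproducibility certificate (phantom randomness and fitting
#' randomness are derived from it).
#'
#' @param phantom A [phantom_config()].
#' @param alpha Angular step in degrees (default 2).
#' @param beta Angular half-range in degrees (default 60).
#' @param spec A [network_spec()].
#' @param fit A [fit_config()].
#' @param sweep Optional named list with numeric `alpha` and/or `beta`
#'   vectors; the driver runs every combination.
#' @param seed Global seed; overrides the phantom and fit seeds.
#' @return A `run_config`.
#' @export
run_config <- function(phantom = phantom_config(), alpha = 2, beta = 60,
                       spec = network_spec(), fit = fit_config(),
                       sweep = NULL, seed = 1L) {
  if (!is.null(sweep)) {
    stopifnot(is.list(sweep), all(names(sweep) %in% c("alpha", "beta")))
  }
  phantom$seed <- as.integer(seed)
  fit$seed <- as.integer(seed) + 1L
  structure(
    list(phantom = phantom, alpha = alpha, beta = beta, spec = spec,
         fit = fit, sweep = sweep, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Serialize / restore a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly;
#'   `read_run_config` a `run_config` equal to the one written.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- list(
    phantom = unclass(config$phantom),
    alpha = config$alpha, beta = config$beta,
    spec = unclass(config$spec), fit = unclass(config$fit),
    sweep = config$sweep, seed = config$seed
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  ph <- do.call(phantom_config, obj$phantom[
    setdiff(names(obj$phantom), character(0))
  ])
  spec <- do.call(network_spec, obj$spec)
  fit <- do.call(fit_config, obj$fit)
  run_config(phantom = ph, alpha = obj$alpha, beta = obj$beta,
             spec = spec, fit = fit, sweep = obj$sweep, seed = obj$seed)
}

#' Simulate a preprocessed ground-truth phantom
#'
#' Generates the binary phantom, smooths it with the configured
#' low-pass filter, and clamps negative densities — the preparation
#' applied to every simulated tomogram before projection.
#'
#' @param pc A [phantom_config()].
#' @return A [volume()].
#' @export
simulate_phantom <- function(pc) {
  v <- generate_phantom(pc)
  objects <- v$objects
  v <- threshold_nonnegative(lowpass_filter(v, cutoff = pc$lowpass_cutoff))
  v$objects <- objects
  v
}

.missing_fraction <- function(dims, g, half_width = 0.5) {
  m <- wedge_masks(dims, g, half_width)
  mean(m$missing)
}

#' Run a reconstruction experiment (optionally an alpha/beta sweep)
#'
#' For every `(alpha, beta)` cell: simulate the phantom, project it at
#' `seq(-beta, beta, alpha)`, normalize the tilt series to `[0, 1]`,
#' reconstruct with both the coordinate-network method and the WBP
#' baseline, affine-calibrate both estimates onto the reference scale
#' (see [calibrate_volume()]), and evaluate all metrics.  A failure in one cell is recorded and the
#' remaining cells still run.
#'
#' @param config A [run_config()].
#' @param methods Character subset of `c("cn", "wbp")`.
#' @param verbose Print per-cell progress.
#' @return A `run_result`: `summary` (one tibble row per cell and
#'   method), `reports` (nested list of `metrics_report`s keyed
#'   `a<alpha>_b<beta>`), and `phantom`.
#' @export
run_experiment <- function(config, methods = c("cn", "wbp"),
                           verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  methods <- match.arg(methods, c("cn", "wbp"), several.ok = TRUE)
  vref <- simulate_phantom(config$phantom)
  z <- dim(vref$data)[3]
  alphas <- config$sweep$alpha %||% config$alpha
  betas <- config$sweep$beta %||% config$beta
  cells <- expand.grid(alpha = alphas, beta = betas)
  rows <- list()
  reports <- list()
  for (ci in seq_len(nrow(cells))) {
    a <- cells$alpha[ci]; b <- cells$beta[ci]
    key <- sprintf("a%g_b%g", a, b)
    if (verbose) message(sprintf("cell %s", key))
    cell <- tryCatch({
      g <- tilt_geometry(step = a, range = b)
      p <- normalize_series(project(vref, g))
      mfrac <- .missing_fraction(dim(vref$data), g)
      out <- list()
      if ("cn" %in% methods) {
        rec <- reconstruct_volume(p, z, spec = config$spec, fit = config$fit)
        out$cn <- evaluate_volumes(calibrate_volume(rec$volume, vref), vref, g)
        out$cn_report <- rec$report
      }
      if ("wbp" %in% methods) {
        vw <- calibrate_volume(wbp_reconstruct(p, z = z), vref)
        out$wbp <- evaluate_volumes(vw, vref, g)
      }
      out$l <- length(g$angles)
      out$missing_fraction <- mfrac
      out
    }, error = function(e) structure(list(msg = conditionMessage(e)),
                                     class = "cell_error"))
    if (inherits(cell, "cell_error")) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        alpha = a, beta = b, l = NA_integer_, method = NA_character_,
        psnr = NA_real_, ssim = NA_real_, vif = NA_real_,
        fsc_full_mean = NA_real_, fsc_present_mean = NA_real_,
        fsc_missing_mean = NA_real_, missing_fraction = NA_real_,
        error = cell$msg
      )
      next
    }
    reports[[key]] <- cell
    for (m in methods) {
      rows[[length(rows) + 1L]] <- cbind(
        tibble::tibble(alpha = a, beta = b, l = cell$l, method = m),
        report_summary(cell[[m]]),
        tibble::tibble(missing_fraction = cell$missing_fraction,
                       error = NA_character_)
      )
    }
  }
  structure(
    list(summary = tibble::as_tibble(do.call(rbind, rows)),
         reports = reports, phantom = vref, config = config),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result>\n")
  print(x$summary)
  invisible(x)
}
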