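# The coordinate network G_theta: R^3 -> R.  A fully connected network
# with sinusoidal activations takes a positionally encoded 3D coordinate
# and returns a density value; evaluating it over a voxel-center grid
# yields a volume.  Frequencies are octave-spaced (2^k) as in standard
# positional encoding; sine layers follow the SIREN initialization
# convention.

#' Coordinate-network architecture
#'
#' @param hidden_layers Number of hidden layers (default 4).
#' @param features Width of each hidden layer (default 256).
#' @param encoding_frequencies Number of positional-encoding octaves L
#'   (default 6); the encoded input has `3 * 2 * L` components
#'   (plus 3 if `include_raw_coords`).
#' @param omega0 Sine frequency scale applied inside every sinusoidal
#'   layer (default 30).
#' @param include_raw_coords Prepend the raw coordinate to the encoding
#'   (default `FALSE`; required when `encoding_frequencies = 0`).
#' @return A `network_spec`.
#' @examples
#' nominal_param_count(network_spec(4, 256)) # 262144
#' @export
network_spec <- function(hidden_layers = 4L, features = 256L,
                         encoding_frequencies = 6L, omega0 = 30,
                         include_raw_coords = FALSE) {
  hidden_layers <- as.integer(hidden_layers)
  features <- as.integer(features)
  encoding_frequencies <- as.integer(encoding_frequencies)
  if (hidden_layers < 1L) stop("`hidden_layers` must be >= 1")
  if (features < 1L) stop("`features` must be >= 1")
  if (encoding_frequencies < 0L) stop("`encoding_frequencies` must be >= 0")
  if (encoding_frequencies == 0L && !include_raw_coords) {
    stop("with 0 encoding frequencies the raw coordinates must be included")
  }
  if (omega0 <= 0) stop("`omega0` must be positive")
  structure(
    list(hidden_layers = hidden_layers, features = features,
         encoding_frequencies = encoding_frequencies, omega0 = omega0,
         include_raw_coords = isTRUE(include_raw_coords)),
    class = "network_spec"
  )
}

#' Nominal parameter count of an architecture
#'
#' The capacity figure used by the subvolume planner:
#' `hidden_layers * features^2`.  This counting convention covers the
#' square hidden weight matrices only; the full trainable count
#' (including input/output layers and biases) is available from
#' [trainable_param_count()].
#'
#' @param spec A [network_spec()].
#' @return Integer-valued count.
#' @export
nominal_param_count <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  spec$hidden_layers * spec$features^2
}

.encoding_dim <- function(spec) {
  3L * 2L * spec$encoding_frequencies + 3L * spec$include_raw_coords
}

#' Exact trainable parameter count
#'
#' @param spec A [network_spec()].
#' @return Total number of weights and biases.
#' @export
trainable_param_count <- function(spec) {
  d <- .encoding_dim(spec)
  f <- spec$features
  h <- spec$hidden_layers
  d * f + f +                      # input layer
    (h - 1L) * (f * f + f) +       # hidden-to-hidden
    f + 1L                         # output layer
}

#' Voxel-center coordinate grid
#'
#' One coordinate per voxel center, each axis mapped affinely onto
#' `[-1, 1]` (a single-voxel axis maps to 0).  Coordinate ordering
#' matches the volume linearization: x fastest, then y, then z.
#'
#' @param dims Integer `(x, y, z)`.
#' @return A `coordinate_set`: list with `coords` (n x 3 matrix) and
#'   `dims`.
#' @export
make_grid <- function(dims) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) {
    stop("`dims` must be three integers >= 1")
  }
  ax <- lapply(dims, function(n) {
    if (n == 1L) 0 else seq(-1, 1, length.out = n)
  })
  coords <- cbind(
    rep(ax[[1]], times = dims[2] * dims[3]),
    rep(rep(ax[[2]], each = dims[1]), times = dims[3]),
    rep(ax[[3]], each = dims[1] * dims[2])
  )
  colnames(coords) <- c("x", "y", "z")
  structure(list(coords = coords, dims = dims), class = "coordinate_set")
}

#' Positional encoding of 3D coordinates
#'
#' Lifts a coordinate `c` in `[-1,1]^3` to
#' `[sin(2^k pi c_i), cos(2^k pi c_i)]` for octaves `k = 0..L-1` over
#' the three components, optionally prepended with the raw coordinate.
#'
#' @param coords Length-3 vector or n x 3 matrix of coordinates.
#' @param L Number of octaves (>= 0).
#' @param include_raw Prepend raw coordinates (default `FALSE`).
#' @return A vector (or n-row matrix) of length `3*2*L` plus 3 if
#'   `include_raw`.
#' @export
positional_encode <- function(coords, L, include_raw = FALSE) {
  if (L < 0) stop("`L` must be >= 0")
  vec <- is.null(dim(coords))
  m <- if (vec) matrix(coords, nrow = 1L) else as.matrix(coords)
  if (ncol(m) != 3L) stop("coordinates must have 3 components")
  parts <- if (include_raw) list(m) else list()
  for (k in seq_len(L) - 1L) {
    arg <- 2^k * pi * m
    parts <- c(parts, list(sin(arg)), list(cos(arg)))
  }
  out <- do.call(cbind, c(parts, list(deparse.level = 0)))
  if (is.null(out)) out <- matrix(numeric(0), nrow = nrow(m), ncol = 0L)
  if (vec) as.numeric(out) else out
}

.encode_set <- function(coords, spec) {
  m <- if (inherits(coords, "coordinate_set")) coords$coords else as.matrix(coords)
  positional_encode(m, spec$encoding_frequencies, spec$include_raw_coords)
}

#' Initialize network parameters
#'
#' Sine-layer-appropriate uniform initialization, deterministic in
#' `seed`: first-layer weights from `U(-1/fan_in, 1/fan_in)`, all later
#' weights from `U(-sqrt(6/fan_in)/omega0, +sqrt(6/fan_in)/omega0)`,
#' and biases from `U(-1/sqrt(fan_in), +1/sqrt(fan_in))`.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return A `network_params` with weight list `W`, bias list `b`, the
#'   `spec`, and the `seed`.
#' @export
init_params <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "network_spec"))
  d <- .encoding_dim(spec)
  f <- spec$features
  fans <- c(d, rep(f, spec$hidden_layers))       # fan_in per weight matrix
  outs <- c(rep(f, spec$hidden_layers), 1L)
  with_seed(seed, {
    W <- vector("list", spec$hidden_layers + 1L)
    b <- vector("list", spec$hidden_layers + 1L)
    for (i in seq_along(W)) {
      bound <- if (i == 1L) 1 / fans[i] else sqrt(6 / fans[i]) / spec$omega0
      W[[i]] <- matrix(runif(fans[i] * outs[i], -bound, bound), fans[i], outs[i])
      b[[i]] <- runif(outs[i], -1 / sqrt(fans[i]), 1 / sqrt(fans[i]))
    }
    structure(list(W = W, b = b, spec = spec, seed = as.integer(seed)),
              class = "network_params")
  })
}

# forward pass keeping pre-activations for backpropagation
.mlp_forward <- function(params, enc) {
  spec <- params$spec
  H <- spec$hidden_layers
  n <- nrow(enc)
  Z <- vector("list", H)
  A <- vector("list", H + 1L)
  A[[1L]] <- enc
  h <- enc
  for (i in seq_len(H)) {
    Z[[i]] <- h %*% params$W[[i]] + rep(params$b[[i]], each = n)
    h <- sin(spec$omega0 * Z[[i]])
    A[[i + 1L]] <- h
  }
  out <- as.numeric(h %*% params$W[[H + 1L]] + params$b[[H + 1L]])
  list(out = out, Z = Z, A = A)
}

# gradients of sum(dout * out) with respect to all weights and biases
.mlp_backward <- function(params, cache, dout) {
  spec <- params$spec
  H <- spec$hidden_layers
  gW <- vector("list", H + 1L)
  gb <- vector("list", H + 1L)
  g <- matrix(dout, ncol = 1L)
  gW[[H + 1L]] <- crossprod(cache$A[[H + 1L]], g)
  gb[[H + 1L]] <- colSums(g)
  g <- g %*% t(params$W[[H + 1L]])
  for (i in rev(seq_len(H))) {
    g <- g * (spec$omega0 * cos(spec$omega0 * cache$Z[[i]]))
    gW[[i]] <- crossprod(cache$A[[i]], g)
    gb[[i]] <- colSums(g)
    if (i > 1L) g <- g %*% t(params$W[[i]])
  }
  list(W = gW, b = gb)
}

#' Evaluate a coordinate network
#'
#' Applies the network pointwise over a coordinate set.  When `coords`
#' carries grid metadata (from [make_grid()]) the result can be reshaped
#' into a volume with [network_volume()].
#'
#' @param params A [init_params()] result (or fitted parameters).
#' @param coords A `coordinate_set` or an n x 3 coordinate matrix.
#' @return Numeric vector of one density value per coordinate.
#' @export
evaluate_network <- function(params, coords) {
  stopifnot(inherits(params, "network_params"))
  enc <- .encode_set(coords, params$spec)
  if (ncol(enc) != nrow(params$W[[1L]])) {
    stop(sprintf("encoded dimension %d does not match first-layer fan-in %d",
                 ncol(enc), nrow(params$W[[1L]])))
  }
  .mlp_forward(params, enc)$out
}

#' Evaluate a network on a voxel grid and return a volume
#'
#' @param params A `network_params`.
#' @param dims Integer `(x, y, z)` grid size.
#' @return A [volume()] of `dims`.
#' @export
network_volume <- function(params, dims) {
  vals <- evaluate_network(params, make_grid(dims))
  volume(array(vals, dims))
}

#' Save / load a network checkpoint
#'
#' Portable checkpoint holding the architecture, the initialization
#' seed, and all weights.
#'
#' @param params A `network_params`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a `network_params`.
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "network_params"))
  saveRDS(unclass(params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  stopifnot(is.list(obj), all(c("W", "b", "spec") %in% names(obj)))
  structure(obj, class = "network_params")
}
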