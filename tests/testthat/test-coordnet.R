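test_that("the voxel grid maps axes affinely onto [-1, 1]", {
  g2 <- make_grid(c(2, 2, 2))
  expect_equal(nrow(g2$coords), 8L)
  expect_true(all(g2$coords %in% c(-1, 1)))
  g31 <- make_grid(c(3, 1, 1))
  expect_equal(g31$coords[, "x"], c(-1, 0, 1))
  expect_true(all(g31$coords[, c("y", "z")] == 0))
  # independent affine-map oracle over all voxels of a 4^3 grid
  g4 <- make_grid(c(4, 4, 4))
  want <- as.matrix(expand.grid(x = 0:3, y = 0:3, z = 0:3)) * 2 / 3 - 1
  expect_equal(unname(g4$coords), unname(want), tolerance = 1e-12)
  expect_error(make_grid(c(0, 4, 4)), ">= 1")
})

test_that("positional encoding matches the octave sinusoid definition", {
  expect_equal(positional_encode(c(0, 0, 0), L = 3),
               rep(c(0, 0, 0, 1, 1, 1), times = 3))
  expect_equal(positional_encode(c(0.3, -0.7, 1), L = 0, include_raw = TRUE),
               c(0.3, -0.7, 1))
  # term-by-term oracle at L = 2
  cc <- c(0.5, -0.25, 1.0)
  got <- positional_encode(cc, L = 2)
  want <- c(sin(pi * cc), cos(pi * cc), sin(2 * pi * cc), cos(2 * pi * cc))
  expect_equal(got, want, tolerance = 1e-12)
  expect_length(got, 3 * 2 * 2)
  expect_error(positional_encode(cc, L = -1), "L")
})

test_that("initialization is seeded, correctly sized, and within bounds", {
  spec <- network_spec(4, 256)
  expect_equal(nominal_param_count(spec), 262144)
  p1 <- init_params(spec, seed = 9)
  p2 <- init_params(spec, seed = 9)
  expect_identical(p1$W, p2$W)
  expect_identical(p1$b, p2$b)
  expect_false(identical(p1$W[[1]], init_params(spec, seed = 10)$W[[1]]))
  # documented bounds, checked exhaustively on a tiny network
  sp <- network_spec(1, 2, encoding_frequencies = 2, omega0 = 30)
  d_in <- 3 * 2 * 2
  pp <- init_params(sp, seed = 1)
  expect_equal(dim(pp$W[[1]]), c(d_in, 2L))
  expect_equal(dim(pp$W[[2]]), c(2L, 1L))
  expect_true(all(abs(pp$W[[1]]) <= 1 / d_in))
  expect_true(all(abs(pp$W[[2]]) <= sqrt(6 / 2) / 30))
  expect_true(all(abs(pp$b[[1]]) <= 1 / sqrt(d_in)))
  expect_true(all(abs(pp$b[[2]]) <= 1 / sqrt(2)))
})

test_that("network evaluation matches a pencil-and-paper forward pass", {
  sp <- network_spec(1, 2, encoding_frequencies = 1, omega0 = 2)
  pp <- init_params(sp, seed = 0)
  pp$W[[1]] <- matrix(seq(0.1, 1.2, by = 0.1), 6, 2)   # enc dim 6
  pp$b[[1]] <- c(0.05, -0.1)
  pp$W[[2]] <- matrix(c(0.7, -0.3), 2, 1)
  pp$b[[2]] <- 0.25
  cc <- matrix(c(0.5, -0.25, 1), 1, 3)
  enc <- c(sin(pi * cc), cos(pi * cc))
  z <- enc %*% pp$W[[1]] + matrix(pp$b[[1]], 1)
  want <- sum(sin(2 * z) * c(0.7, -0.3)) + 0.25
  expect_equal(evaluate_network(pp, cc), as.numeric(want), tolerance = 1e-12)
  # zeroed output layer: constant bias everywhere
  pp$W[[2]][] <- 0
  vals <- evaluate_network(pp, make_grid(c(3, 3, 3)))
  expect_true(all(vals == 0.25))
})

test_that("evaluation is deterministic and consistent across grid refinement", {
  sp <- network_spec(2, 8, encoding_frequencies = 3)
  pp <- init_params(sp, seed = 2)
  g <- make_grid(c(5, 5, 5))
  expect_identical(evaluate_network(pp, g), evaluate_network(pp, g))
  # shared coordinates of a 2x-finer grid evaluate identically
  coarse <- array(evaluate_network(pp, g), c(5, 5, 5))
  fine <- array(evaluate_network(pp, make_grid(c(9, 9, 9))), c(9, 9, 9))
  expect_equal(coarse, fine[seq(1, 9, 2), seq(1, 9, 2), seq(1, 9, 2)],
               tolerance = 1e-12)
})

test_that("analytic gradients of the reprojection loss match finite differences", {
  sp <- network_spec(1, 4, encoding_frequencies = 1, omega0 = 3)
  pp <- init_params(sp, seed = 5)
  dims <- c(3L, 2L, 3L)
  g <- make_grid(dims)
  angles <- c(-30, 0, 45)
  A <- projector_matrix(dims[1], dims[3], angles)
  set.seed(6)
  target <- matrix(rnorm(nrow(A) * dims[2]), nrow(A), dims[2])

  loss_fn <- function(p) {
    out <- evaluate_network(p, g)
    V2 <- matrix(aperm(array(out, dims), c(1, 3, 2)), dims[1] * dims[3], dims[2])
    mean((as.matrix(A %*% V2) - target)^2)
  }
  # analytic gradient through the adjoint and the MLP backward pass
  enc <- cryocn:::.encode_set(g, sp)
  fw <- cryocn:::.mlp_forward(pp, enc)
  V2 <- matrix(aperm(array(fw$out, dims), c(1, 3, 2)),
               dims[1] * dims[3], dims[2])
  resid <- 2 * (as.matrix(A %*% V2) - target) / length(target)
  dV2 <- as.matrix(Matrix::crossprod(A, resid))
  dout <- as.vector(aperm(array(dV2, c(dims[1], dims[3], dims[2])), c(1, 3, 2)))
  gr <- cryocn:::.mlp_backward(pp, fw, dout)

  h <- 1e-6
  for (li in 1:2) {
    idx <- cbind(c(1, nrow(pp$W[[li]])), c(1, ncol(pp$W[[li]])))
    for (r in seq_len(nrow(idx))) {
      pa <- pp; pa$W[[li]][idx[r, 1], idx[r, 2]] <- pa$W[[li]][idx[r, 1], idx[r, 2]] + h
      pb <- pp; pb$W[[li]][idx[r, 1], idx[r, 2]] <- pb$W[[li]][idx[r, 1], idx[r, 2]] - h
      fd <- (loss_fn(pa) - loss_fn(pb)) / (2 * h)
      an <- gr$W[[li]][idx[r, 1], idx[r, 2]]
      expect_lt(abs(fd - an) / max(abs(fd), 1e-8), 1e-4)
    }
  }
})

test_that("checkpoints round-trip the architecture and weights", {
  sp <- network_spec(2, 6, encoding_frequencies = 2)
  pp <- init_params(sp, seed = 3)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(pp, path)
  qq <- load_checkpoint(path)
  expect_identical(qq$W, pp$W)
  expect_identical(qq$spec$features, sp$features)
  g <- make_grid(c(4, 4, 2))
  expect_identical(evaluate_network(qq, g), evaluate_network(pp, g))
})
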