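test_that("the subvolume planner reproduces the parameter-to-voxel rule", {
  # full-scale worked example: 1024x1024x256 with the default network
  pl <- plan_subvolumes(c(1024, 1024, 256), network_spec(4, 256), 1 / 8)
  expect_equal(pl$width, 8L)
  expect_equal(pl$n_subvolumes, 128L)
  expect_true(all(pl$intervals$width == 8L))
  # degenerate: network capacity covers the whole volume
  pl1 <- plan_subvolumes(c(8, 8, 4), network_spec(4, 256), 1 / 8)
  expect_equal(pl1$n_subvolumes, 1L)
  expect_equal(pl1$width, 8L)
  # exhaustive-search oracle on a non-dyadic volume
  dims <- c(360L, 360L, 360L)
  spec <- network_spec(4, 256)
  cand <- 2^(0:20)
  cand <- cand[cand <= dims[2]]
  ok <- cand[nominal_param_count(spec) / (dims[1] * cand * dims[3]) >= 1 / 8]
  expect_equal(plan_subvolumes(dims, spec, 1 / 8)$width, max(ok))
  # intervals tile y without overlap, last one may be narrower
  pl2 <- plan_subvolumes(c(16, 13, 8), network_spec(1, 8), 1 / 8)
  expect_equal(sum(pl2$intervals$width), 13L)
  expect_equal(pl2$intervals$y_start,
               head(c(0L, cumsum(pl2$intervals$width)), -1))
})

test_that("tilt-series slices concatenate back to the original series", {
  g <- tilt_geometry(angles = c(-20, 0, 20))
  set.seed(8)
  p <- tilt_series(array(rnorm(16 * 13 * 3), c(16, 13, 3)), g)
  pl <- plan_subvolumes(c(16, 13, 8), network_spec(1, 8), 1 / 8)
  expect_gt(pl$n_subvolumes, 1L)
  # concatenating all slices restores the series bit-exactly
  glued <- array(0, dim(p$images))
  for (i in seq_len(pl$n_subvolumes)) {
    iv <- pl$intervals[i, ]
    glued[, (iv$y_start + 1):iv$y_end, ] <- slice_series(p, pl, i)$images
  }
  expect_identical(glued, p$images)
  for (i in seq_len(pl$n_subvolumes)) {
    iv <- pl$intervals[i, ]
    expect_identical(slice_series(p, pl, i)$images,
                     p$images[, (iv$y_start + 1):iv$y_end, , drop = FALSE])
  }
  # single-subvolume plan returns the full series
  pl1 <- plan_subvolumes(c(16, 13, 8), network_spec(4, 64), 1 / 8)
  expect_identical(slice_series(p, pl1, 1)$images, p$images)
  expect_error(slice_series(p, pl, pl$n_subvolumes + 1L), "out of range")
})

test_that("the learning-rate schedule decays geometrically", {
  expect_equal(lr_schedule(0, 100, 1e-3, 1e-4), 1e-3)
  expect_equal(lr_schedule(99, 100, 1e-3, 1e-4), 1e-4)
  expect_equal(lr_schedule(0:4, 5, 2e-3, 2e-3), rep(2e-3, 5))
  # geometric mean at the midpoint of an odd-length schedule
  expect_equal(lr_schedule(2, 5, 1e-3, 1e-4), sqrt(1e-3 * 1e-4),
               tolerance = 1e-12)
  expect_equal(lr_schedule(0, 1, 5e-4, 1e-5), 5e-4)
  expect_error(lr_schedule(5, 5, 1e-3, 1e-4), "step")
  sched <- lr_schedule(0:199, 200, 1e-3, 1e-4)
  expect_true(all(diff(sched) < 0))
})

test_that("a network fitting its own reprojections starts at the optimum", {
  sp <- network_spec(1, 8, encoding_frequencies = 2)
  pp <- init_params(sp, seed = 4)
  g <- tilt_geometry(angles = c(-40, 0, 40))
  v0 <- network_volume(pp, c(12, 4, 8))
  p0 <- project(v0, g)
  ft <- fit_config(iterations_adjacent = 50, seed = 4)
  f <- suppressWarnings(fit_subvolume(p0, 8, sp, ft, init = pp))
  expect_lt(f$loss_trace[1], 1e-8)
  expect_lt(f$final_loss, f$loss_trace[1] + 1e-6)
})

test_that("a zero tilt series is fitted to numerical zero", {
  g <- tilt_geometry(angles = seq(-60, 60, 20))
  p <- tilt_series(array(0, c(16, 8, 7)), g)
  sp <- network_spec(1, 16, encoding_frequencies = 2)
  f <- fit_subvolume(p, 8, sp, fit_config(seed = 2))   # default schedule
  expect_lt(f$final_loss, 1e-4)
})

test_that("a fully sampled ball subvolume is fitted below reprojection noise", {
  # full +/-90 degree coverage at 1 degree steps: no missing wedge, so
  # the network should essentially solve the inverse problem
  gt <- volume(sphere_shell_mask(c(32, 8, 32), c(15.5, 3.5, 15.5), 14, NULL))
  g <- tilt_geometry(step = 1, range = 90)
  p <- normalize_series(project(gt, g))
  sp <- network_spec(2, 32, encoding_frequencies = 5)
  f <- fit_subvolume(p, 32, sp, fit_config(seed = 7))
  expect_lt(f$final_loss, 1e-3)
  cn <- calibrate_volume(network_volume(f$params, c(32, 8, 32)), gt)
  wbp <- calibrate_volume(wbp_reconstruct(p, z = 32), gt)
  expect_gt(psnr(cn, gt), psnr(wbp, gt))
})

test_that("the default iteration policy is 2000 cold then 400 warm steps", {
  pc <- phantom_config("spheres", dims = c(16, 16, 8), n_objects = 2,
                       diameter_range = c(4, 6), seed = 21)
  p <- normalize_series(project(simulate_phantom(pc), tilt_geometry(step = 10)))
  sp <- network_spec(1, 8, encoding_frequencies = 3)
  rec <- reconstruct_volume(p, 8, spec = sp, fit = fit_config(seed = 1))
  expect_equal(rec$plan$n_subvolumes, 4L)
  expect_equal(rec$report$iterations, c(2000L, 400L, 400L, 400L))
  expect_equal(rec$report$warm, c(FALSE, TRUE, TRUE, TRUE))
  # reprojection error decreases on every subvolume
  expect_true(all(rec$report$loss_final < rec$report$loss_initial))
  # stitched estimate has the right shape and finite values
  expect_equal(dim(rec$volume), c(16L, 16L, 8L))
  expect_true(all(is.finite(rec$volume$data)))
})

test_that("a one-subvolume plan reduces to a single fit", {
  pc <- phantom_config("spheres", dims = c(16, 8, 8), n_objects = 1,
                       diameter_range = c(5, 6), seed = 3)
  p <- normalize_series(project(simulate_phantom(pc),
                                tilt_geometry(step = 15)))
  sp <- network_spec(2, 16, encoding_frequencies = 3)
  ft <- fit_config(iterations_first = 120, seed = 6)
  rec <- reconstruct_volume(p, 8, spec = sp, fit = ft)
  expect_equal(rec$plan$n_subvolumes, 1L)
  f <- fit_subvolume(p, 8, sp, ft)
  expect_equal(rec$volume$data,
               array(evaluate_network(f$params, make_grid(c(16, 8, 8))),
                     c(16, 8, 8)),
               tolerance = 1e-12)
})

test_that("reconstruction is deterministic in the seed", {
  pc <- phantom_config("spheres", dims = c(16, 8, 8), n_objects = 1,
                       diameter_range = c(5, 6), seed = 3)
  p <- normalize_series(project(simulate_phantom(pc), tilt_geometry(step = 15)))
  sp <- network_spec(1, 8, encoding_frequencies = 2)
  ft <- fit_config(iterations_first = 80, seed = 9)
  r1 <- reconstruct_volume(p, 8, spec = sp, fit = ft)
  r2 <- reconstruct_volume(p, 8, spec = sp, fit = ft)
  expect_identical(r1$volume$data, r2$volume$data)
})

test_that("coordinate batching still descends on the reprojection loss", {
  pc <- phantom_config("spheres", dims = c(16, 16, 8), n_objects = 2,
                       diameter_range = c(4, 6), seed = 13)
  p <- normalize_series(project(simulate_phantom(pc), tilt_geometry(step = 10)))
  sp <- network_spec(1, 16, encoding_frequencies = 3)
  ft <- fit_config(iterations_first = 400, seed = 2,
                   coords_per_step = 16 * 8 * 4)   # half the y-slices
  f <- fit_subvolume(p, 8, sp, ft)
  expect_lt(median(tail(f$loss_trace, 50)), 0.1 * median(head(f$loss_trace, 10)))
})

test_that("total-variation regularization is accepted and keeps the fit finite", {
  g <- tilt_geometry(angles = seq(-60, 60, 30))
  set.seed(10)
  p <- normalize_series(tilt_series(array(runif(12 * 4 * 5), c(12, 4, 5)), g))
  sp <- network_spec(1, 8, encoding_frequencies = 2)
  ft <- fit_config(iterations_first = 100, lambda = 1e-3,
                   regularizer = "total_variation", seed = 1)
  f <- fit_subvolume(p, 6, sp, ft)
  expect_true(all(is.finite(f$loss_trace)))
  expect_lt(f$final_loss, f$loss_trace[1])
})
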