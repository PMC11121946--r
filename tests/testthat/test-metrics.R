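make_vol <- function(dims, seed = 1, fun = runif) {
  set.seed(seed)
  volume(array(fun(prod(dims)), dims))
}

test_that("PSNR follows its closed form and scale invariance", {
  v <- make_vol(c(8, 8, 8))
  expect_equal(psnr(v, v), Inf)
  a <- volume(array(0.5, c(8, 8, 8)))
  b <- volume(array(0, c(8, 8, 8)))
  expect_equal(psnr(a, b, im = 1), 10 * log10(1 / 0.25), tolerance = 1e-12)
  expect_equal(psnr(a, b, im = 1), 6.0206, tolerance = 1e-4)
  # scaling both volumes and Im together leaves PSNR unchanged
  w <- make_vol(c(8, 8, 8), seed = 2)
  p1 <- psnr(v, w, im = 1)
  v3 <- volume(3 * v$data); w3 <- volume(3 * w$data)
  expect_equal(psnr(v3, w3, im = 3), p1, tolerance = 1e-12)
  expect_error(psnr(v, make_vol(c(8, 8, 4))), "dimensions differ")
})

test_that("SSIM matches a direct windowed-statistics oracle", {
  v <- make_vol(c(16, 16, 16), seed = 3)
  expect_equal(ssim(v, v), 1, tolerance = 1e-12)
  # anticorrelated zero-mean volumes score negative (a sinusoid keeps
  # the local means near zero so the covariance term sets the sign)
  gx <- sin(2 * pi * (0:15) / 4)
  z <- volume(array(rep(gx, 16 * 16), c(16, 16, 16)))
  zneg <- volume(-z$data)
  expect_lt(ssim(zneg, z, K1 = 0.1, data_range = 2), 0)
  # independent brute-force implementation on a random pair
  a <- make_vol(c(16, 16, 16), seed = 5)
  b <- volume(a$data + 0.15 * array(rnorm(16^3), dim(a$data)))
  expect_equal(ssim(b, a), ssim_bruteforce(b$data, a$data), tolerance = 1e-6)
  expect_error(ssim(make_vol(c(8, 8, 8)), make_vol(c(8, 8, 8))), "window larger")
})

test_that("VIF is 1 at identity, below 1 for blur, and matches slices", {
  a <- make_vol(c(32, 32, 32), seed = 6)
  expect_equal(as.numeric(vif(a, a)), 1, tolerance = 1e-8)
  blur <- lowpass_filter(a, 0.3)
  vb <- as.numeric(vif(blur, a))
  expect_gt(vb, 0)
  expect_lt(vb, 1)
  expect_error(vif(a, volume(array(1, c(32, 32, 32)))), "constant reference")
  # slice-wise 2D reference averaged over z, documented tolerance 0.15
  v3 <- as.numeric(vif(blur, a))
  v2 <- mean(vapply(seq_len(32), function(iz) {
    vif2d(a$data[, , iz], blur$data[, , iz])
  }, numeric(1)))
  expect_lt(abs(v3 - v2), 0.15)
})

test_that("FSC is 1 for identical or rescaled volumes and ~0 for noise", {
  v <- make_vol(c(16, 16, 16), seed = 7, fun = rnorm)
  cv <- fsc(v, v)
  expect_true(all(abs(cv$correlation - 1) < 1e-10))
  expect_true(all(diff(cv$shell) > 0))
  expect_true(all(cv$n_voxels > 0))
  cv2 <- fsc(volume(2 * v$data), v)
  expect_true(all(abs(cv2$correlation - 1) < 1e-10))
  # independent white-noise volumes: per-shell correlation within the
  # sampling-error bound 3/sqrt(n) on well-populated shells
  n1 <- make_vol(c(32, 32, 32), seed = 8, fun = rnorm)
  n2 <- make_vol(c(32, 32, 32), seed = 9, fun = rnorm)
  cn <- fsc(n1, n2)
  big <- cn$n_voxels >= 100
  expect_true(all(abs(cn$correlation[big]) <= 3 / sqrt(cn$n_voxels[big])))
})

test_that("wedge masks partition Fourier space with Hermitian symmetry", {
  g <- tilt_geometry(step = 2, range = 60)
  m <- wedge_masks(c(16, 16, 16), g)
  expect_true(all(xor(m$present, m$missing)))
  flip <- function(a) {
    n <- dim(a)
    a[c(1, n[1]:2), c(1, n[2]:2), c(1, n[3]:2)]
  }
  expect_identical(m$present, flip(m$present))
  expect_identical(m$missing, flip(m$missing))
  # full angular coverage with fine sampling leaves nothing missing
  mfull <- wedge_masks(c(16, 16, 16), tilt_geometry(step = 2, range = 90))
  expect_true(all(!mfull$missing))
})

test_that("the missing fraction approaches the analytic wedge solid angle", {
  g <- tilt_geometry(step = 2, range = 60)
  dims <- c(64, 64, 64)
  m <- wedge_masks(dims, g)
  si <- cryocn:::.shell_index(dims)
  sel <- si$shell >= 16 & si$shell <= 26   # slabs overlap out to ~r 28
  frac <- mean(m$missing[sel])
  # double wedge of half-angle 30 degrees: solid-angle fraction 1/3
  expect_lt(abs(frac - 1 / 3) / (1 / 3), 0.15)
})

test_that("widening the angular range strictly shrinks the missing wedge", {
  dims <- c(32, 32, 32)
  prev <- NULL
  for (beta in c(30, 45, 60)) {
    m <- wedge_masks(dims, tilt_geometry(step = 2, range = beta))
    if (!is.null(prev)) {
      expect_true(all(prev$missing[m$missing]))  # containment
      expect_lt(sum(m$missing), sum(prev$missing))
    }
    prev <- m
  }
})

test_that("directional FSC isolates corruption confined to the wedge", {
  dims <- c(32, 32, 32)
  g <- tilt_geometry(step = 2, range = 60)
  m <- wedge_masks(dims, g)
  v1 <- make_vol(dims, seed = 10, fun = rnorm)
  d1 <- directional_fsc(v1, v1, m, "present")
  d2 <- directional_fsc(v1, v1, m, "missing")
  expect_true(all(abs(d1$correlation - 1) < 1e-10))
  expect_true(all(abs(d2$correlation - 1) < 1e-10))
  # replace the missing-region coefficients with independent noise
  # (Hermitian by construction: the FFT of a real noise volume)
  F1 <- fft(v1$data)
  set.seed(11)
  N <- fft(array(rnorm(prod(dims), sd = stats::sd(v1$data)), dims))
  v2 <- volume(Re(fft(F1 * m$present + N * m$missing, inverse = TRUE)) /
                 prod(dims))
  dp <- directional_fsc(v2, v1, m, "present")
  dm <- directional_fsc(v2, v1, m, "missing")
  expect_true(all(dp$correlation > 0.99))
  big <- dm$n_voxels >= 100
  expect_true(all(abs(dm$correlation[big]) < 3.5 / sqrt(dm$n_voxels[big])))
  # per-shell voxel counts of the two regions partition the full FSC's
  cf <- fsc(v2, v1)
  counts <- merge(as.data.frame(dp[, c("shell", "n_voxels")]),
                  as.data.frame(dm[, c("shell", "n_voxels")]),
                  by = "shell", all = TRUE)
  counts[is.na(counts)] <- 0L
  cmp <- merge(counts, as.data.frame(cf[, c("shell", "n_voxels")]), by = "shell")
  expect_equal(cmp$n_voxels.x + cmp$n_voxels.y, cmp$n_voxels)
})

test_that("a self-comparison report is perfect on every metric", {
  v <- make_vol(c(32, 32, 32), seed = 12)
  rep <- evaluate_volumes(v, v, tilt_geometry())
  expect_equal(rep$psnr, Inf)
  expect_equal(rep$ssim, 1, tolerance = 1e-10)
  expect_equal(as.numeric(rep$vif), 1, tolerance = 1e-8)
  expect_true(all(abs(rep$fsc_full$correlation - 1) < 1e-10))
  expect_true(all(abs(rep$fsc_missing$correlation - 1) < 1e-10))
  s <- report_summary(rep)
  expect_equal(s$ssim, 1, tolerance = 1e-10)
})

test_that("elongation anisotropy separates isotropic from stretched objects", {
  ball <- volume(sphere_shell_mask(c(24, 24, 24), c(11.5, 11.5, 11.5), 12, NULL))
  expect_lt(abs(elongation_anisotropy(ball) - 1), 0.2)
  d <- c(24, 24, 24)
  grid <- expand.grid(x = 0:23, y = 0:23, z = 0:23)
  ell <- (grid$x - 11.5)^2 / 16 + (grid$y - 11.5)^2 / 16 +
    (grid$z - 11.5)^2 / 100 <= 1
  vell <- volume(array(as.numeric(ell), d))
  expect_gt(elongation_anisotropy(vell), 1.5)
})
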