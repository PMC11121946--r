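# Shared fixtures and independent oracles for the test suite.
# Heavy artifacts (the scaled-down method-validation run) are computed
# once per session and cached here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Study-condition fixture: 64 x 64 x 32 hollow-sphere slab, 2 degree
# steps over +/-60 degrees, reduced network (2 layers x 64 features),
# full 2000/400 protocol.  Used by the method-validation tests.
sphere_fixture <- function() {
  cached("sphere_fixture", {
    pc <- phantom_config("spheres", dims = c(64, 64, 32), n_objects = 5,
                         diameter_range = c(10, 18), seed = 11)
    vref <- simulate_phantom(pc)
    g <- tilt_geometry(step = 2, range = 60)
    p <- normalize_series(project(vref, g))
    list(vref = vref, g = g, p = p,
         spec = network_spec(2, 64), fit = fit_config(seed = 3))
  })
}

# Coordinate-network reconstruction of the sphere fixture (expensive;
# one run shared by every test that needs it)
sphere_fixture_cn <- function() {
  cached("sphere_fixture_cn", {
    fx <- sphere_fixture()
    reconstruct_volume(fx$p, 32, spec = fx$spec, fit = fx$fit)
  })
}

# cold-start fit of the second subvolume with the full 2000-iteration
# protocol (reference for the learned-initialization comparison)
sphere_fixture_cold2000 <- function() {
  cached("sphere_fixture_cold2000", {
    fx <- sphere_fixture()
    plan <- plan_subvolumes(c(dim(fx$p$images)[1:2], 32L), fx$spec, 1 / 8)
    ps2 <- slice_series(fx$p, plan, 2)
    fit_subvolume(ps2, 32, fx$spec,
                  fit_config(iterations_first = 2000, seed = fx$fit$seed))
  })
}

sphere_fixture_wbp <- function() {
  cached("sphere_fixture_wbp", {
    fx <- sphere_fixture()
    normalize_volume(wbp_reconstruct(fx$p, z = 32))
  })
}

# dense projector built column by column from unit basis slices — an
# independent realization of the operator used for linearity/adjoint
# checks
dense_projector <- function(x, z, angles) {
  n <- x * z
  P <- matrix(0, length(angles) * x, n)
  for (i in seq_len(n)) {
    e <- numeric(n)
    e[i] <- 1
    v <- volume(array(e, c(x, 1, z)))
    P[, i] <- as.vector(project(v, tilt_geometry(angles = angles))$images)
  }
  P
}

# independent 6-connected component count (plain BFS over an index set)
count_components_bfs <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  ncomp <- 0L
  for (s in idx) {
    if (lab[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    lab[s] <- ncomp
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      i0 <- cur - 1L
      ix <- i0 %% d[1]; iy <- (i0 %/% d[1]) %% d[2]; iz <- i0 %/% (d[1] * d[2])
      for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                       c(0, 0, -1), c(0, 0, 1))) {
        nx <- ix + off[1]; ny <- iy + off[2]; nz <- iz + off[3]
        if (nx < 0 || ny < 0 || nz < 0 ||
            nx >= d[1] || ny >= d[2] || nz >= d[3]) next
        nb <- 1L + nx + d[1] * (ny + d[2] * nz)
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- ncomp
          queue <- c(queue, nb)
        }
      }
    }
  }
  ncomp
}

# brute-force local-window SSIM (direct loops; independent of the
# package's separable-convolution implementation)
ssim_bruteforce <- function(a, b, sigma = 1.5, win = 11L,
                            K1 = 0.01, K2 = 0.03, data_range = NULL) {
  if (is.null(data_range)) data_range <- diff(range(b))
  off <- seq_len(win) - (win + 1) / 2
  k1d <- exp(-off^2 / (2 * sigma^2))
  k3 <- outer(outer(k1d, k1d), k1d)
  k3 <- k3 / sum(k3)
  d <- dim(a)
  m <- d - win + 1L
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  vals <- numeric(prod(m))
  q <- 0L
  for (kz in seq_len(m[3])) for (ky in seq_len(m[2])) for (kx in seq_len(m[1])) {
    wa <- a[kx:(kx + win - 1), ky:(ky + win - 1), kz:(kz + win - 1)]
    wb <- b[kx:(kx + win - 1), ky:(ky + win - 1), kz:(kz + win - 1)]
    mu1 <- sum(k3 * wa); mu2 <- sum(k3 * wb)
    s11 <- sum(k3 * wa * wa) - mu1^2
    s22 <- sum(k3 * wb * wb) - mu2^2
    s12 <- sum(k3 * wa * wb) - mu1 * mu2
    q <- q + 1L
    vals[q] <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
      ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  }
  mean(vals)
}

# independent 2D pixel-domain multiscale VIF for one slice (reference
# implementation for the slice-averaged cross-check)
vif2d <- function(ref, dist, sigma_nsq = 2) {
  eps <- 1e-10
  conv2_valid <- function(m, k) {
    len <- length(k)
    band <- function(n) {
      K <- matrix(0, n - len + 1L, n)
      for (jj in seq_len(len)) {
        K[cbind(seq_len(n - len + 1L), seq_len(n - len + 1L) + jj - 1L)] <- k[jj]
      }
      K
    }
    t(band(ncol(m)) %*% t(band(nrow(m)) %*% m))
  }
  num <- 0; den <- 0
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    off <- seq_len(N) - (N + 1) / 2
    k <- exp(-off^2 / (2 * (N / 5)^2)); k <- k / sum(k)
    if (scale > 1) {
      if (any(dim(ref) < N)) break
      ref <- conv2_valid(ref, k)
      dist <- conv2_valid(dist, k)
      ref <- ref[seq(1, nrow(ref), 2), seq(1, ncol(ref), 2), drop = FALSE]
      dist <- dist[seq(1, nrow(dist), 2), seq(1, ncol(dist), 2), drop = FALSE]
    }
    if (any(dim(ref) < N)) break
    mu1 <- conv2_valid(ref, k); mu2 <- conv2_valid(dist, k)
    s1 <- pmax(conv2_valid(ref * ref, k) - mu1^2, 0)
    s2 <- pmax(conv2_valid(dist * dist, k) - mu2^2, 0)
    s12 <- conv2_valid(ref * dist, k) - mu1 * mu2
    g <- s12 / (s1 + eps)
    sv <- s2 - g * s12
    g[s1 < eps] <- 0; sv[s1 < eps] <- s2[s1 < eps]; s1[s1 < eps] <- 0
    g[s2 < eps] <- 0; sv[s2 < eps] <- 0
    sv[g < 0] <- s2[g < 0]; g[g < 0] <- 0
    sv[sv <= eps] <- eps
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  num / den
}

# nearest-neighbourless bilinear resampling rotation of a volume about
# the y-axis (independent oracle for rotation-consistency checks)
rotate_vol_y <- function(v, theta_deg) {
  d <- dim(v$data)
  th <- theta_deg * pi / 180
  cx <- (d[1] - 1) / 2; cz <- (d[3] - 1) / 2
  out <- array(0, d)
  gx <- seq_len(d[1]) - 1 - cx
  gz <- seq_len(d[3]) - 1 - cz
  # inverse map: sample source at R(-theta) applied to target coords
  for (izt in seq_len(d[3])) {
    zt <- gz[izt]
    sx <- cx + gx * cos(th) + zt * sin(th)
    sz <- cz - gx * sin(th) + zt * cos(th)
    x0 <- floor(sx); fx <- sx - x0
    z0 <- floor(sz); fz <- sz - z0
    for (dx in 0:1) for (dz in 0:1) {
      xi <- x0 + dx; zi <- z0 + dz
      w <- (if (dx == 1) fx else 1 - fx) * (if (dz == 1) fz else 1 - fz)
      ok <- xi >= 0 & xi < d[1] & zi >= 0 & zi < d[3] & w > 0
      if (!any(ok)) next
      src <- v$data[cbind(rep(xi[ok] + 1L, d[2]),
                          rep(seq_len(d[2]), each = sum(ok)),
                          rep(zi[ok] + 1L, d[2]))]
      contrib <- matrix(src, sum(ok), d[2]) * w[ok]
      out[which(ok), , izt] <- out[which(ok), , izt] + contrib
    }
  }
  volume(out)
}
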