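test_that("constant volume has zero Hessian eigenvalues everywhere", {
  v <- volume_grid(array(42, c(12, 12, 12)), c(1, 1, 1))
  eig <- hessian_eigenvalues(v, sigma = 1)
  expect_equal(max(abs(eig$l1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(eig$l3)), 0, tolerance = 1e-12)
})

test_that("Gaussian blob eigenvalues match the closed form at the centre", {
  # image A*exp(-r^2/(2 s^2)) smoothed at sigma: normalised second
  # derivative at the centre is -sigma^2 * A * s^3 / (s^2 + sigma^2)^(5/2)
  d <- c(33, 33, 33); ctr <- c(17, 17, 17); s <- 2.5; A <- 50; sigma <- 1.0
  g <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  r2 <- rowSums(sweep(g, 2, ctr)^2)
  v <- volume_grid(array(A * exp(-r2 / (2 * s^2)), dim = d), c(1, 1, 1))
  eig <- hessian_eigenvalues(v, sigma)
  expected <- -sigma^2 * A * s^3 / (s^2 + sigma^2)^(5 / 2)
  got <- c(eig$l1[17, 17, 17], eig$l2[17, 17, 17], eig$l3[17, 17, 17])
  expect_equal(got, rep(expected, 3), tolerance = 2e-2)
  expect_true(all(got < 0))
})

test_that("tube eigenstructure: |l1| small, l2 ~ l3 < 0 on the axis", {
  v <- make_tube_volume(c(24, 24, 24), p1 = c(12, 12, 2), p2 = c(12, 12, 22),
                        sigma = 1)
  eig <- hessian_eigenvalues(v, sigma = 1)
  i <- c(13, 13, 12)  # on-axis voxel (1-based)
  l1 <- eig$l1[i[1], i[2], i[3]]; l2 <- eig$l2[i[1], i[2], i[3]]
  l3 <- eig$l3[i[1], i[2], i[3]]
  expect_lt(abs(l1), 0.1 * abs(l2))
  expect_lt(l2, 0); expect_lt(l3, 0)
  expect_equal(l2 / l3, 1, tolerance = 0.1)
})

test_that("separable Hessian matches dense brute-force convolution (16^3)", {
  set.seed(5)
  x <- array(rnorm(16^3), c(16, 16, 16))
  v <- volume_grid(x, c(1, 1, 1))
  for (sigma in c(0.7, 1.3)) {
    oracle <- brute_hessian(x, sigma)
    g0 <- pvsmorph:::gaussian_kernel(sigma, 0L)
    g1 <- pvsmorph:::gaussian_kernel(sigma, 1L)
    g2 <- pvsmorph:::gaussian_kernel(sigma, 2L)
    sn <- sigma^2
    sep <- list(
      xx = pvsmorph:::cpp_sep_conv3d(x, dim(x), g2, g0, g0) * sn,
      yy = pvsmorph:::cpp_sep_conv3d(x, dim(x), g0, g2, g0) * sn,
      zz = pvsmorph:::cpp_sep_conv3d(x, dim(x), g0, g0, g2) * sn,
      xy = pvsmorph:::cpp_sep_conv3d(x, dim(x), g1, g1, g0) * sn,
      xz = pvsmorph:::cpp_sep_conv3d(x, dim(x), g1, g0, g1) * sn,
      yz = pvsmorph:::cpp_sep_conv3d(x, dim(x), g0, g1, g1) * sn)
    for (nm in names(oracle)) {
      rel <- max(abs(sep[[nm]] - oracle[[nm]])) / max(abs(oracle[[nm]]))
      expect_lt(rel, 1e-6, label = sprintf("sigma %.1f comp %s", sigma, nm))
    }
  }
})

test_that("eigenvalue kernel agrees with base::eigen on random matrices", {
  set.seed(8)
  n <- 200
  a <- rnorm(n); b <- rnorm(n); c3 <- rnorm(n)
  d <- rnorm(n); e <- rnorm(n); f <- rnorm(n)
  got <- pvsmorph:::cpp_sym3_eigen(a, b, c3, d, e, f)
  for (i in seq_len(n)) {
    M <- matrix(c(a[i], d[i], e[i], d[i], b[i], f[i], e[i], f[i], c3[i]), 3)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[order(abs(ev))]
    expect_equal(c(got$l1[i], got$l2[i], got$l3[i]), ev, tolerance = 1e-9)
  }
})

test_that("vesselness functional: polarity gate and analytic substitutions", {
  p <- frangi_params(alpha = 0.5, beta_b = 0.5, c = 1)
  as_field <- function(l1, l2, l3)
    list(l1 = array(l1, c(1, 1, 1)), l2 = array(l2, c(1, 1, 1)),
         l3 = array(l3, c(1, 1, 1)))
  # positive l2 -> 0 (bright-on-dark polarity)
  expect_equal(as.vector(vesselness_at_scale(as_field(0, 1, -2), p)), 0)
  expect_equal(as.vector(vesselness_at_scale(as_field(0, -1, 2), p)), 0)
  # ideal tube (0, -L, -L): Ra = 1, Rb = 0; with c tiny relative to S the
  # structureness factor is 1 within double precision -> V = 1 - exp(-2)
  L <- 10
  ptiny <- frangi_params(alpha = 0.5, beta_b = 0.5, c = 1e-6)
  v_tube <- as.vector(vesselness_at_scale(as_field(0, -L, -L), ptiny))
  expect_equal(v_tube, 1 - exp(-2), tolerance = 1e-9)
  # sphere (-L, -L, -L): Rb = 1 suppresses by exp(-1/(2 beta^2)) = exp(-2)
  v_sphere <- as.vector(vesselness_at_scale(as_field(-L, -L, -L), ptiny))
  expect_equal(v_sphere / v_tube, exp(-2) * (1 - exp(-1 / 0.5)) / (1 - exp(-2)),
               tolerance = 1e-9)
})

test_that("auto c errors on a zero-curvature field with guidance", {
  v <- volume_grid(array(1, c(8, 8, 8)), c(1, 1, 1))
  eig <- hessian_eigenvalues(v, 1)
  expect_error(vesselness_at_scale(eig, frangi_params(c = "auto")),
               "auto")
})

test_that("single-scale multiscale equals vesselness_at_scale; argmax recorded", {
  v <- make_tube_volume(c(20, 20, 20), c(10, 10, 2), c(10, 10, 18), sigma = 1)
  p1s <- frangi_params(scales_sigma = 1.0, c = 1)
  f <- multiscale_vesselness(v, p1s)
  eig <- hessian_eigenvalues(v, 1.0)
  expect_equal(f$data, vesselness_at_scale(eig, p1s), tolerance = 1e-12)
  expect_true(all(f$scale_of_max[f$data > 0] == 1.0))
})

test_that("thin and thick tubes are both detected, each at its own scale", {
  d <- c(40, 40, 24)
  v1 <- make_tube_volume(d, c(10, 10, 2), c(10, 10, 22), sigma = 0.75)
  v2 <- make_tube_volume(d, c(28, 28, 2), c(28, 28, 22), sigma = 2.0)
  v <- volume_grid(v1$data + v2$data, c(1, 1, 1))
  p <- frangi_params(scales_sigma = c(0.4, 0.7, 1.0, 1.3, 2.0), c = "auto")
  f <- multiscale_vesselness(v, p)
  s_thin <- f$scale_of_max[11, 11, 12]
  s_thick <- f$scale_of_max[29, 29, 12]
  expect_gt(f$data[11, 11, 12], 0.1)
  expect_gt(f$data[29, 29, 12], 0.1)
  expect_lt(s_thin, s_thick)
})

test_that("response across scales is unimodal around the matched scale", {
  # sweep restricted to sigma >= 0.7: below that the sampled derivative
  # kernels overestimate curvature (sub-voxel aliasing), which inflates
  # the response non-monotonically
  v <- make_tube_volume(c(24, 24, 24), c(12, 12, 2), c(12, 12, 22), sigma = 1.4)
  resp <- sapply(c(0.7, 1.0, 1.4, 2.0, 2.8, 3.8), function(s) {
    eig <- hessian_eigenvalues(v, s)
    # c chosen well above the structureness range so the S term, which
    # carries the scale selectivity here, does not saturate; evaluated on
    # the tube axis mid-point (the global max picks up end-cap edges)
    vesselness_at_scale(eig, frangi_params(c = 50))[13, 13, 12]
  })
  peak <- which.max(resp)
  expect_true(peak %in% 2:4)
  expect_true(all(diff(resp[1:peak]) > 0))
  expect_true(all(diff(resp[peak:length(resp)]) < 0))
})

test_that("vesselness is rotation-robust within 10% at matched scale", {
  d <- c(36, 36, 36)
  ax <- make_tube_volume(d, c(18, 18, 4), c(18, 18, 32), sigma = 1)
  # 45 degrees in the x-z plane, same length
  L <- 28 / sqrt(2)
  rot <- make_tube_volume(d, c(18 - L / 2, 18, 18 - L / 2),
                          c(18 + L / 2, 18, 18 + L / 2), sigma = 1)
  p <- frangi_params(scales_sigma = 1.0, c = 100)
  v_ax <- max(multiscale_vesselness(ax, p)$data)
  v_rot <- max(multiscale_vesselness(rot, p)$data)
  expect_lt(abs(v_ax - v_rot) / v_ax, 0.10)
})

test_that("scaling contrast never decreases vesselness at fixed c", {
  set.seed(21)
  x <- array(rnorm(12^3), c(12, 12, 12))
  p <- frangi_params(c = 5)
  for (k in c(1.5, 3)) {
    v1 <- multiscale_vesselness(volume_grid(x, c(1, 1, 1)), p)$data
    v2 <- multiscale_vesselness(volume_grid(k * x, c(1, 1, 1)), p)$data
    expect_true(all(v2 - v1 >= -1e-12), label = sprintf("k = %.1f", k))
  }
})
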