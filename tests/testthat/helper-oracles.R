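# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: dense (non-separable) convolution, explicit
# covariance accumulation, and direct formula evaluation.

# symmetric half-sample reflection, 1-based
reflect1 <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j[j < 0] <- j[j < 0] + 2L * n
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

# Dense 3-D convolution with the full outer-product kernel, reflection
# boundary. Loops over kernel offsets, vectorised over the volume.
brute_conv3 <- function(x, kx, ky, kz) {
  d <- dim(x)
  rx <- (length(kx) - 1L) / 2L
  ry <- (length(ky) - 1L) / 2L
  rz <- (length(kz) - 1L) / 2L
  out <- array(0, dim = d)
  for (a in seq_along(kx)) {
    ia <- reflect1(seq_len(d[1]) + (a - 1L - rx), d[1])
    for (b in seq_along(ky)) {
      ib <- reflect1(seq_len(d[2]) + (b - 1L - ry), d[2])
      kxy <- kx[a] * ky[b]
      for (cc in seq_along(kz)) {
        ic <- reflect1(seq_len(d[3]) + (cc - 1L - rz), d[3])
        out <- out + (kxy * kz[cc]) * x[ia, ib, ic]
      }
    }
  }
  out
}

# Brute-force Hessian oracle: all six components by dense convolution with
# the same sampled Gaussian-derivative kernels as the implementation, times
# the sigma^gamma normalisation.
brute_hessian <- function(x, sigma, gamma_norm = 2) {
  g0 <- pvsmorph:::gaussian_kernel(sigma, 0L)
  g1 <- pvsmorph:::gaussian_kernel(sigma, 1L)
  g2 <- pvsmorph:::gaussian_kernel(sigma, 2L)
  sn <- sigma^gamma_norm
  list(xx = brute_conv3(x, g2, g0, g0) * sn,
       yy = brute_conv3(x, g0, g2, g0) * sn,
       zz = brute_conv3(x, g0, g0, g2) * sn,
       xy = brute_conv3(x, g1, g1, g0) * sn,
       xz = brute_conv3(x, g1, g0, g1) * sn,
       yz = brute_conv3(x, g0, g1, g1) * sn)
}

# Moment oracle: explicit covariance accumulation over the voxel list,
# population normalisation, +1/12 voxel-extent correction, axes 4*sqrt(ev).
brute_axes <- function(vox, spacing = c(1, 1, 1)) {
  pts <- sweep(vox, 2, spacing, `*`)
  n <- nrow(pts)
  mu <- colMeans(pts)
  S <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    v <- pts[i, ] - mu
    S <- S + tcrossprod(v)
  }
  S <- S / n + diag(spacing^2 / 12)
  sort(4 * sqrt(pmax(eigen(S, symmetric = TRUE)$values, 0)), decreasing = TRUE)
}

# Straight tube phantom on an isotropic grid for filter tests: radial
# Gaussian profile around a segment, flat ends.
make_tube_volume <- function(d = c(32, 32, 32), p1, p2, sigma = 1,
                             amp = 100, background = 0) {
  g <- as.matrix(expand.grid(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1,
                             z = seq_len(d[3]) - 1))
  u <- p2 - p1
  len2 <- sum(u * u)
  w <- sweep(g, 2, p1)
  t <- drop(w %*% u) / len2
  rad2 <- rowSums((w - outer(t, u))^2)
  val <- ifelse(t >= 0 & t <= 1, amp * exp(-rad2 / (2 * sigma^2)), 0)
  volume_grid(array(background + val, dim = d), c(1, 1, 1))
}

# small phantom spec used across tests; dots override the small defaults
small_phantom_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(grid_shape = c(48L, 48L, 24L), voxel_spacing_mm = c(1, 1, 2),
         n_pvs = 3L, pvs_length_range_mm = c(5, 18),
         pvs_radius_range_voxels = c(0.6, 1.1),
         noise_sigma = 0, seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

# Match accepted components to phantom truth structures by centroid ->
# centerline distance; returns data frame of measured vs true quantities.
match_components_to_truth <- function(accepted, truth) {
  if (!length(accepted)) return(NULL)
  rows <- lapply(accepted, function(cmp) {
    cen <- (cmp$centroid - 1)          # voxel i sits at (i-1) mm, iso grid
    dists <- vapply(truth$centerlines, function(m) {
      if (nrow(m) == 1L) sqrt(sum((cen - m[1, ])^2))
      else pvsmorph:::point_seg_dist(matrix(cen, 1), m[1, ], m[2, ])
    }, numeric(1))
    k <- which.min(dists)
    data.frame(true_id = truth$structures$id[k],
               class = truth$structures$class[k],
               true_length = truth$structures$length_mm[k],
               true_radius = truth$structures$radius_mm[k],
               meas_length = cmp$axis_lengths_mm[1],
               meas_width = cmp$axis_lengths_mm[2],
               dist = dists[k])
  })
  do.call(rbind, rows)
}
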