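#' Specification for a synthetic PVS phantom volume
#'
#' Describes a T2w-like volume containing bright tubular perivascular-space
#' (PVS) analogues and optional bright blob-like white-matter-hyperintensity
#' (WMH) confounders, plus noise. Defaults follow the acquisition geometry of
#' the cohort the pipeline targets: a 256 x 256 x 80 matrix at 1 x 1 x 2 mm
#' (1 mm in-plane, 2 mm slice thickness). Tubes have a Gaussian cross-section
#' of standard deviation `pvs_radius_range_voxels` (in-plane voxels = mm);
#' the default radius band 0.5-1.25 voxels yields apparent widths in the
#' 0.5-2.5 voxel band that the multiscale filter is designed to enhance.
#'
#' @param grid_shape integer 3-vector of voxel counts, all >= 8.
#' @param voxel_spacing_mm positive spacing triple in mm.
#' @param n_pvs number of tubes; default 258 matches the mean per-subject
#'   PVS count observed in the cohort regime at full grid size.
#' @param pvs_length_range_mm tube length interval (mm).
#' @param pvs_radius_range_voxels Gaussian cross-section sigma interval
#'   (in-plane voxels).
#' @param n_wmh_blobs number of spherical confounders.
#' @param wmh_radius_range_mm blob sigma interval (mm).
#' @param background_mean baseline intensity.
#' @param pvs_contrast peak intensity increment of tubes (and blobs).
#' @param noise_sigma noise standard deviation; 0 disables noise.
#' @param noise_model `"gaussian"` or `"rician"` (magnitude of signal plus
#'   complex Gaussian, the usual MRI magnitude model).
#' @param artefact `"none"` or `"parallel_streaks"` (thin bright lines along
#'   the phase axis mimicking motion artefacts; used to exercise QC flags).
#' @param orient_max_deg maximum tube tilt from the through-plane (z) axis,
#'   degrees; centrum semiovale vessels run roughly dorsoventrally.
#' @param seed integer RNG seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(256L, 256L, 80L),
                         voxel_spacing_mm = c(1, 1, 2),
                         n_pvs = 258L,
                         pvs_length_range_mm = c(3, 50),
                         pvs_radius_range_voxels = c(0.5, 1.25),
                         n_wmh_blobs = 0L,
                         wmh_radius_range_mm = c(2, 4),
                         background_mean = 100,
                         pvs_contrast = 100,
                         noise_sigma = 5,
                         noise_model = c("gaussian", "rician"),
                         artefact = c("none", "parallel_streaks"),
                         orient_max_deg = 40,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  artefact <- match.arg(artefact)
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_spacing_mm = as.numeric(voxel_spacing_mm),
               n_pvs = as.integer(n_pvs),
               pvs_length_range_mm = as.numeric(pvs_length_range_mm),
               pvs_radius_range_voxels = as.numeric(pvs_radius_range_voxels),
               n_wmh_blobs = as.integer(n_wmh_blobs),
               wmh_radius_range_mm = as.numeric(wmh_radius_range_mm),
               background_mean = background_mean,
               pvs_contrast = pvs_contrast,
               noise_sigma = noise_sigma,
               noise_model = noise_model,
               artefact = artefact,
               orient_max_deg = orient_max_deg,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (length(s$grid_shape) != 3L || any(s$grid_shape < 8L))
    stop("grid_shape must be three integers, all >= 8")
  if (any(s$voxel_spacing_mm <= 0)) stop("voxel spacing must be positive")
  if (s$n_pvs < 0L || s$n_wmh_blobs < 0L) stop("structure counts must be >= 0")
  extent <- s$grid_shape * s$voxel_spacing_mm
  if (s$n_pvs > 0L) {
    if (s$pvs_length_range_mm[1] <= 0 ||
        s$pvs_length_range_mm[2] > max(extent))
      stop("pvs_length_range_mm must lie within (0, grid extent]")
    if (diff(s$pvs_length_range_mm) < 0) stop("pvs_length_range_mm reversed")
  }
  if (any(s$pvs_radius_range_voxels <= 0) || any(s$wmh_radius_range_mm <= 0))
    stop("radii must be positive")
  if (s$pvs_contrast <= 0) stop("pvs_contrast must be positive")
  if (s$noise_sigma < 0) stop("noise_sigma must be >= 0")
  invisible(s)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Minimum distance between two 3-D segments (p1-p2, q1-q2).
seg_seg_dist <- function(p1, p2, q1, q2) {
  u <- p2 - p1; v <- q2 - q1; w <- p1 - q1
  a <- sum(u * u); b <- sum(u * v); c <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  D <- a * c - b * b
  if (D < 1e-12) { sc <- 0; tc <- if (c > 1e-12) e / c else 0 }
  else { sc <- (b * e - c * d) / D; tc <- (a * e - b * d) / D }
  sc <- min(max(sc, 0), 1); tc <- min(max(tc, 0), 1)
  # clamp-and-refine once for the boundary cases
  if (a > 1e-12) sc <- min(max((b * tc - d) / a, 0), 1)
  if (c > 1e-12) tc <- min(max((b * sc + e) / c, 0), 1)
  sqrt(sum((p1 + sc * u - q1 - tc * v)^2))
}

# Distance from points (n x 3 matrix, mm) to segment p1-p2.
point_seg_dist <- function(pts, p1, p2) {
  u <- p2 - p1
  len2 <- sum(u * u)
  w <- sweep(pts, 2, p1)
  t <- if (len2 > 0) pmin(pmax((w %*% u) / len2, 0), 1) else rep(0, nrow(pts))
  proj <- outer(as.vector(t), u) + matrix(p1, nrow(pts), 3, byrow = TRUE)
  sqrt(rowSums((pts - proj)^2))
}

#' Generate a synthetic phantom volume with ground truth
#'
#' Draws `n_pvs` bright tubes (analytic Gaussian cross-section sampled at
#' voxel centres, no anti-aliasing) and `n_wmh_blobs` bright isotropic
#' Gaussian blobs inside a rectangular region-of-interest mask, then adds
#' noise and optional streak artefacts. Tubes are straight segments tilted
#' at most `orient_max_deg` from the z axis and are placed with a minimum
#' clearance between structures so each remains a distinct connected
#' component after segmentation. The volume is built in native anisotropic
#' space so reslicing is genuinely exercised downstream.
#'
#' @param spec a [phantom_spec].
#' @return list with `volume` ([volume_grid]), `truth` (`phantom_truth`:
#'   data frame of structures plus a list of centerlines in mm), and `roi`
#'   (binary [volume_grid] in native space).
#' @export
generate_volume <- function(spec) {
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    d <- spec$grid_shape
    sp <- spec$voxel_spacing_mm
    vol <- array(spec$background_mean, dim = d)
    extent <- d * sp

    # rectangular ROI inset from the grid edge (voxel-centre coordinates:
    # voxel i sits at (i-1)*spacing mm)
    inset <- c(4, 4, 6)
    roi_lo <- pmin(inset, extent / 4)
    roi_hi <- pmax(extent - sp - inset, roi_lo + sp)
    roi <- array(FALSE, dim = d)
    ctr <- lapply(1:3, function(ax) (seq_len(d[ax]) - 1) * sp[ax])
    inside <- lapply(1:3, function(ax) ctr[[ax]] >= roi_lo[ax] & ctr[[ax]] <= roi_hi[ax])
    roi[inside[[1]], inside[[2]], inside[[3]]] <- TRUE

    structures <- list()
    centerlines <- list()
    min_clear <- 3  # mm clearance between structure surfaces

    clearance_ok <- function(p1, p2, r) {
      for (s in structures) {
        q <- centerlines[[s$id]]
        dmin <- if (nrow(q) == 1L)
          min(point_seg_dist(q, p1, p2)) else
          seg_seg_dist(p1, p2, q[1, ], q[2, ])
        if (dmin < (r + s$radius_mm) * 2 + min_clear) return(FALSE)
      }
      TRUE
    }

    # Gaussian radial profile around the segment p1-p2, flat-ended: voxels
    # whose axial projection falls outside [0, L] get no signal, so the
    # drawn tube has the stated length rather than spherical caps. A
    # degenerate segment (p1 == p2) yields an isotropic Gaussian blob.
    add_gaussian_tube <- function(p1, p2, sigma, amp) {
      pad <- 4 * sigma
      lo <- pmax(floor((pmin(p1, p2) - pad) / sp) + 1, 1)
      hi <- pmin(ceiling((pmax(p1, p2) + pad) / sp) + 1, d)
      ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
      g <- as.matrix(expand.grid(x = (ix - 1) * sp[1], y = (iy - 1) * sp[2],
                                 z = (iz - 1) * sp[3]))
      u <- p2 - p1
      len2 <- sum(u * u)
      w <- sweep(g, 2, p1)
      if (len2 > 0) {
        t <- drop(w %*% u) / len2
        inside <- t >= 0 & t <= 1
        rad2 <- rowSums((w - outer(t, u))^2)
        add <- ifelse(inside, amp * exp(-rad2 / (2 * sigma^2)), 0)
      } else {
        add <- amp * exp(-rowSums(w^2) / (2 * sigma^2))
      }
      vol[ix, iy, iz] <<- vol[ix, iy, iz] +
        array(add, dim = c(length(ix), length(iy), length(iz)))
    }

    next_id <- 0L
    place <- function(class) {
      for (try in seq_len(200L)) {
        if (class == "PVS") {
          L <- runif(1, spec$pvs_length_range_mm[1], spec$pvs_length_range_mm[2])
          r <- runif(1, spec$pvs_radius_range_voxels[1],
                     spec$pvs_radius_range_voxels[2]) * sp[1]
          theta <- runif(1, 0, spec$orient_max_deg * pi / 180)
          phi <- runif(1, 0, 2 * pi)
          dir <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
          if (any(roi_lo + 3 * r >= roi_hi - 3 * r)) next
          p1 <- runif(3, roi_lo + 3 * r, roi_hi - 3 * r)
          p2 <- p1 + L * dir
          if (any(p2 < roi_lo + 3 * r) || any(p2 > roi_hi - 3 * r)) next
          if (!clearance_ok(p1, p2, r)) next
          next_id <<- next_id + 1L
          add_gaussian_tube(p1, p2, r, spec$pvs_contrast)
          structures[[next_id]] <<- list(id = next_id, class = "PVS",
                                         radius_mm = r, length_mm = L)
          centerlines[[next_id]] <<- rbind(p1, p2)
          return(TRUE)
        } else {
          r <- runif(1, spec$wmh_radius_range_mm[1], spec$wmh_radius_range_mm[2])
          if (any(roi_lo + 3 * r >= roi_hi - 3 * r)) next
          p <- runif(3, roi_lo + 3 * r, roi_hi - 3 * r)
          if (!clearance_ok(p, p, r)) next
          next_id <<- next_id + 1L
          add_gaussian_tube(p, p, r, spec$pvs_contrast)
          structures[[next_id]] <<- list(id = next_id, class = "WMH",
                                         radius_mm = r, length_mm = 0)
          centerlines[[next_id]] <<- rbind(p)
          return(TRUE)
        }
      }
      FALSE
    }

    for (i in seq_len(spec$n_pvs))
      if (!place("PVS"))
        stop("phantom placement failed: grid too small/crowded for ",
             spec$n_pvs, " tubes")
    for (i in seq_len(spec$n_wmh_blobs))
      if (!place("WMH"))
        stop("phantom placement failed for WMH blob")

    if (spec$artefact == "parallel_streaks") {
      n_streak <- 6L
      xs <- sample(which(inside[[1]]), n_streak, replace = TRUE)
      zs <- sample(which(inside[[3]]), n_streak, replace = TRUE)
      for (s in seq_len(n_streak))
        vol[xs[s], , zs[s]] <- vol[xs[s], , zs[s]] + 0.8 * spec$pvs_contrast
    }

    if (spec$noise_sigma > 0) {
      n <- length(vol)
      if (spec$noise_model == "gaussian") {
        vol <- vol + array(rnorm(n, 0, spec$noise_sigma), dim = d)
      } else {
        re <- vol + array(rnorm(n, 0, spec$noise_sigma), dim = d)
        im <- array(rnorm(n, 0, spec$noise_sigma), dim = d)
        vol <- sqrt(re^2 + im^2)
      }
    }

    truth_df <- if (length(structures)) {
      data.frame(id = vapply(structures, `[[`, 0L, "id"),
                 class = vapply(structures, `[[`, "", "class"),
                 radius_mm = vapply(structures, `[[`, 0, "radius_mm"),
                 length_mm = vapply(structures, `[[`, 0, "length_mm"))
    } else {
      data.frame(id = integer(), class = character(),
                 radius_mm = numeric(), length_mm = numeric())
    }
    truth <- structure(list(structures = truth_df,
                            centerlines = centerlines,
                            roi_mask_ref = "roi"),
                       class = "phantom_truth")
    list(volume = volume_grid(vol, sp),
         truth = truth,
         roi = volume_grid(array(as.numeric(roi), dim = d), sp))
  })
}

#' Write a phantom truth catalog to JSON
#'
#' @param truth a `phantom_truth` as returned by [generate_volume].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  recs <- lapply(seq_len(nrow(truth$structures)), function(i) {
    r <- truth$structures[i, ]
    list(id = r$id, class = r$class, radius_mm = r$radius_mm,
         length_mm = r$length_mm,
         centerline = apply(truth$centerlines[[r$id]], 1, as.numeric,
                            simplify = FALSE))
  })
  jsonlite::write_json(list(roi_mask_ref = truth$roi_mask_ref,
                            structures = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
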