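#' Ellipsoid axis lengths of a voxel set
#'
#' Morphometry follows the ellipsoid-of-equal-second-moments convention:
#' the covariance matrix of the voxel centre coordinates is computed with
#' the population (1/N) normalisation, a per-axis `spacing^2 / 12` term is
#' added to account for the finite extent of each voxel, and each axis
#' length is `4 * sqrt(eigenvalue)` — the axis of the uniform ellipsoid
#' with the same second moments. "Length" is the major axis, "width" the
#' second axis (perpendicular to it). The correction makes degenerate
#' inputs well-defined: a single voxel yields three equal axes
#' `4 * sqrt(1/12) ~ 1.155`, and an N-voxel collinear line yields a major
#' axis `4 * sqrt(N^2 / 12)`.
#'
#' @param voxels n x 3 matrix of voxel coordinates (grid units), or a
#'   `pvs_component`.
#' @param spacing voxel spacing (mm); default 1 mm isotropic.
#' @return numeric descending triple of axis lengths (mm):
#'   (length, width, third axis).
#' @export
#' @examples
#' ellipsoid_axes(matrix(c(1, 1, 1), 1))            # 1.1547 x3
#' ellipsoid_axes(cbind(1:10, 1, 1))                # major axis 11.547
ellipsoid_axes <- function(voxels, spacing = c(1, 1, 1)) {
  if (inherits(voxels, "pvs_component")) voxels <- voxels$voxels
  if (is.null(dim(voxels))) voxels <- matrix(voxels, nrow = 1)
  stopifnot(ncol(voxels) == 3, nrow(voxels) >= 1)
  pts <- sweep(voxels, 2, spacing, `*`)
  n <- nrow(pts)
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  cov_pop <- crossprod(cen) / n + diag(spacing^2 / 12)
  ev <- eigen(cov_pop, symmetric = TRUE, only.values = TRUE)$values
  sort(4 * sqrt(pmax(ev, 0)), decreasing = TRUE)
}

#' Emulate the ordinal visual rating from segmented components
#'
#' The visual scale scores the burden of perivascular spaces from the count
#' seen in the single axial slice judged to contain the most of them, per
#' hemisphere: 0 (none), 1 (mild, 1-10), 2 (moderate, 11-20), 3 (frequent,
#' 21-40), 4 (severe, more than 40). Computationally, a component counts
#' towards a slice if at least one of its voxels lies in it; hemispheres
#' are split at the ROI x-centroid (grid x-midline when no ROI is given),
#' and the maximum over all (slice, hemisphere) pairs is banded.
#'
#' @param components accepted components (with voxel coordinates).
#' @param roi optional binary [volume_grid] used for the hemisphere split.
#' @return list with `max_slice_count`, `max_slice_index`, `rating` (0-4).
#' @export
emulate_visual_rating <- function(components, roi = NULL) {
  if (length(components) == 0L)
    return(list(max_slice_count = 0L, max_slice_index = NA_integer_,
                rating = 0L))
  mid <- if (!is.null(roi)) {
    stopifnot_volume(roi)
    idx <- which(roi$data != 0, arr.ind = TRUE)
    mean(idx[, 1])
  } else {
    mean(range(do.call(rbind, lapply(components, `[[`, "voxels"))[, 1]))
  }
  tallies <- new.env(parent = emptyenv())
  for (cmp in components) {
    hemi <- if (cmp$centroid[1] < mid) "L" else "R"
    for (z in unique(cmp$voxels[, 3])) {
      key <- paste0(hemi, z)
      tallies[[key]] <- (if (is.null(tallies[[key]])) 0L else tallies[[key]]) + 1L
    }
  }
  keys <- ls(tallies)
  counts <- vapply(keys, function(k) tallies[[k]], integer(1))
  best <- which.max(counts)
  n <- counts[[best]]
  rating <- if (n == 0L) 0L else if (n <= 10L) 1L else if (n <= 20L) 2L
    else if (n <= 40L) 3L else 4L
  list(max_slice_count = as.integer(n),
       max_slice_index = as.integer(sub("^[LR]", "", keys[best])),
       rating = rating)
}

#' Per-subject summary of accepted components
#'
#' Aggregates per-component morphometry into the per-subject measures used
#' in the cohort analysis: count, total volume, and mean / median / SD /
#' percentiles (5, 25, 75, 95) of length, width and size, plus the
#' max-slice count and the emulated 0-4 rating. An empty component list
#' yields count 0, zero totals, and `NA` feature statistics (undefined, not
#' zero).
#'
#' @param components accepted components of one subject.
#' @param roi optional ROI for the hemisphere split of the rating.
#' @return a one-row data frame (`subject_summary`).
#' @export
summarize_subject <- function(components, roi = NULL) {
  feat_stats <- function(x) {
    if (length(x) == 0L)
      return(c(mean = NA_real_, median = NA_real_, sd = NA_real_,
               p5 = NA_real_, p25 = NA_real_, p75 = NA_real_, p95 = NA_real_))
    q <- stats::quantile(x, c(.05, .25, .75, .95), names = FALSE, type = 7)
    c(mean = mean(x), median = stats::median(x),
      sd = if (length(x) > 1) stats::sd(x) else 0,
      p5 = q[1], p25 = q[2], p75 = q[3], p95 = q[4])
  }
  lens <- vapply(components, function(cm) cm$axis_lengths_mm[1], numeric(1))
  wids <- vapply(components, function(cm) cm$axis_lengths_mm[2], numeric(1))
  sizes <- vapply(components, function(cm) cm$size_mm3, numeric(1))
  vr <- emulate_visual_rating(components, roi)
  out <- data.frame(count = length(components),
                    total_volume_mm3 = sum(sizes),
                    max_slice_count = vr$max_slice_count,
                    max_slice_index = vr$max_slice_index,
                    emulated_rating = vr$rating)
  for (f in c("length", "width", "size")) {
    s <- feat_stats(switch(f, length = lens, width = wids, size = sizes))
    for (nm in names(s)) out[[paste(f, nm, sep = "_")]] <- s[[nm]]
  }
  class(out) <- c("subject_summary", class(out))
  out
}

#' Per-component morphometry table
#'
#' @param components list of components.
#' @return data frame with one row per component: id, size, axis lengths,
#'   centroid, slice span.
#' @export
component_table <- function(components) {
  if (!length(components))
    return(data.frame(id = integer(), size_voxels = integer(),
                      size_mm3 = numeric(), length_mm = numeric(),
                      width_mm = numeric(), third_axis_mm = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      centroid_z = numeric(), slice_span = integer()))
  do.call(rbind, lapply(components, function(cm) {
    data.frame(id = cm$id, size_voxels = cm$size_voxels,
               size_mm3 = cm$size_mm3,
               length_mm = cm$axis_lengths_mm[1],
               width_mm = cm$axis_lengths_mm[2],
               third_axis_mm = cm$axis_lengths_mm[3],
               centroid_x = cm$centroid[1], centroid_y = cm$centroid[2],
               centroid_z = cm$centroid[3], slice_span = cm$slice_span)
  }))
}
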