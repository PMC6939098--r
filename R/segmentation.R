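#' Threshold a vesselness field
#'
#' @param field a `vesselness_field` from [multiscale_vesselness].
#' @param t threshold in (0, 1); voxels with response >= t are foreground.
#' @param roi optional binary [volume_grid]; the mask is restricted to it.
#' @return binary [volume_grid].
#' @export
threshold_field <- function(field, t, roi = NULL) {
  if (!inherits(field, "vesselness_field")) stop("not a vesselness_field")
  if (t <= 0 || t >= 1) stop("threshold must be in (0,1)")
  m <- (field$data >= t) * 1
  if (!is.null(roi)) {
    stopifnot_volume(roi)
    m <- m * (roi$data != 0)
  }
  volume_grid(m, field$spacing)
}

#' Extract connected components from a binary mask
#'
#' Components are labelled under 26-connectivity (face, edge or corner
#' adjacency): thin oblique tubes fragment under 6-connectivity, so the
#' permissive neighbourhood is the default for tubular structures.
#'
#' @param mask binary [volume_grid] on the isotropic grid.
#' @param connectivity 26 (default) or 6.
#' @return list of `pvs_component` objects, each with `id`, `voxels`
#'   (n x 3 integer matrix of 1-based coordinates), `size_voxels`,
#'   `size_mm3`, `axis_lengths_mm` (descending triple), `centroid`,
#'   `slice_span`.
#' @export
extract_components <- function(mask, connectivity = 26L) {
  stopifnot_volume(mask)
  d <- dim(mask$data)
  m <- mask$data != 0
  m[is.na(m)] <- FALSE
  lab <- if (connectivity == 26L) {
    cpp_label26(m, d)
  } else if (connectivity == 6L) {
    label6_r(m, d)
  } else stop("connectivity must be 6 or 26")
  k <- max(lab)
  if (k == 0L) return(list())
  idx <- which(lab > 0)
  coords <- arrayInd(idx, d)
  labs <- lab[idx]
  ord <- order(labs)
  coords <- coords[ord, , drop = FALSE]
  labs <- labs[ord]
  bounds <- c(0L, cumsum(tabulate(labs, k)))
  vox_mm3 <- prod(mask$spacing)
  lapply(seq_len(k), function(i) {
    vox <- coords[(bounds[i] + 1):bounds[i + 1], , drop = FALSE]
    axes <- ellipsoid_axes(vox, spacing = mask$spacing)
    structure(list(id = i,
                   voxels = vox,
                   size_voxels = nrow(vox),
                   size_mm3 = nrow(vox) * vox_mm3,
                   axis_lengths_mm = axes,
                   centroid = colMeans(vox),
                   slice_span = diff(range(vox[, 3])) + 1L),
              class = "pvs_component")
  })
}

# Reference 6-connectivity labeling (breadth-first in R); used for the
# configurable strict neighbourhood and as a cross-check in tests.
label6_r <- function(m, d) {
  lab <- array(0L, dim = d)
  nextlab <- 0L
  off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in which(m & lab == 0L)) {
    if (lab[s] != 0L) next
    nextlab <- nextlab + 1L
    queue <- s
    lab[s] <- nextlab
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(v, d)
      for (o in seq_len(6)) {
        nb <- ci + off[o, ]
        if (any(nb < 1L) || any(nb > d)) next
        w <- ((nb[3] - 1L) * d[2] + (nb[2] - 1L)) * d[1] + nb[1]
        if (m[w] && lab[w] == 0L) { lab[w] <- nextlab; queue <- c(queue, w) }
      }
    }
  }
  lab
}

#' Filter components by the tubular-structure morphological constraints
#'
#' Accepted perivascular-space candidates must have ellipsoid major-axis
#' length between `min_length_mm` and `max_length_mm` inclusive, and at most
#' `max_size_voxels` voxels. The default volume ceiling of 1000 voxels is
#' the approximate volume of a cylinder of radius 2.5 and length 50 voxels
#' (pi * 2.5^2 * 50 ~ 982, rounded to the nearest hundred) and separates PVS
#' from larger blob-like hyperintensities. Width is not re-applied as a hard
#' rule: the filter's scale band already constrains it softly.
#'
#' @param components list from [extract_components].
#' @param min_length_mm,max_length_mm inclusive length bounds (mm).
#' @param max_size_voxels inclusive volume bound (voxels).
#' @return list with `accepted` (components) and `rejections` (data frame
#'   `id`, `reason` in \{"min-length", "max-length", "max-volume"\}; the
#'   first rule that fired is recorded).
#' @export
filter_components <- function(components, min_length_mm = 3,
                              max_length_mm = 50, max_size_voxels = 1000) {
  if (min_length_mm > max_length_mm) stop("min_length_mm > max_length_mm")
  acc <- list()
  rej_id <- integer(); rej_reason <- character()
  for (cmp in components) {
    len <- cmp$axis_lengths_mm[1]
    reason <- if (cmp$size_voxels > max_size_voxels) "max-volume"
      else if (len < min_length_mm) "min-length"
      else if (len > max_length_mm) "max-length"
      else NA_character_
    if (is.na(reason)) acc[[length(acc) + 1L]] <- cmp
    else { rej_id <- c(rej_id, cmp$id); rej_reason <- c(rej_reason, reason) }
  }
  list(accepted = acc,
       rejections = data.frame(id = rej_id, reason = rej_reason))
}

#' Automated quality-control flags for a segmentation
#'
#' Advisory proxies for the visual QC that rejected noisy or artefactual
#' scans: segmentation is never auto-dropped, the flags only mark subjects
#' for review.
#'
#' @param mask binary segmentation [volume_grid].
#' @param roi binary ROI [volume_grid] on the same grid.
#' @param components accepted components.
#' @param noise_frac flag `noise_suspect` when the segmented fraction of the
#'   ROI exceeds this (default 0.05).
#' @param roi_floor_voxels flag `empty_roi` below this ROI volume.
#' @param blob_axis_ratio flag `blob_suspect` when any accepted component
#'   has length/width below this (WMH-like roundness).
#' @return list of logical flags plus the measured quantities.
#' @export
qc_flags <- function(mask, roi, components, noise_frac = 0.05,
                     roi_floor_voxels = 64, blob_axis_ratio = 1.5) {
  stopifnot_volume(mask); stopifnot_volume(roi)
  roi_n <- sum(roi$data != 0)
  seg_n <- sum(mask$data != 0, na.rm = TRUE)
  frac <- if (roi_n > 0) seg_n / roi_n else 0
  ratios <- vapply(components,
                   function(cmp) cmp$axis_lengths_mm[1] /
                     max(cmp$axis_lengths_mm[2], .Machine$double.eps),
                   numeric(1))
  list(noise_suspect = frac > noise_frac,
       empty_roi = roi_n < roi_floor_voxels,
       blob_suspect = length(ratios) > 0 && any(ratios < blob_axis_ratio),
       segmented_fraction = frac,
       roi_voxels = roi_n,
       min_axis_ratio = if (length(ratios)) min(ratios) else NA_real_)
}
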