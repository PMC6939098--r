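#' Reslice an anisotropic volume to 1 mm isotropic
#'
#' Implements the slice-doubling interpolation used for axial T2w data
#' acquired at 1 mm in-plane and 2 mm slice thickness: every original slice
#' is kept bit-exactly, and a new slice is inserted between each adjacent
#' pair whose voxels are the arithmetic mean of the voxels directly above
#' and below. The output has depth 2Z - 1 (the rule defines inserted voxels
#' only *between* existing slices; no final slice is extrapolated) and
#' spacing 1 x 1 x 1 mm.
#'
#' The function refuses input that is not 1 x 1 x 2 mm: the rule is specific
#' to doubling, and silently re-interpolating already-isotropic data would
#' corrupt it.
#'
#' @param vol a [volume_grid] with spacing (1, 1, 2) mm and >= 2 slices.
#' @param pad_last_slice if `TRUE`, duplicate the final slice to give an
#'   even slice count (2Z); default `FALSE`.
#' @return isotropic [volume_grid], depth `2*Z - 1` (or `2*Z` when padded).
#' @export
#' @examples
#' v <- volume_grid(array(rep(c(10, 20), each = 16), c(4, 4, 2)), c(1, 1, 2))
#' r <- reslice_isotropic(v)
#' r$data[1, 1, ]  # 10 15 20
reslice_isotropic <- function(vol, pad_last_slice = FALSE) {
  stopifnot_volume(vol)
  sp <- vol$spacing
  if (!isTRUE(all.equal(sp[1:2], c(1, 1))) || !isTRUE(all.equal(sp[3], 2)))
    stop("reslice_isotropic expects 1 x 1 mm in-plane and 2 mm slices; got ",
         paste(signif(sp, 4), collapse = " x "),
         " mm (the insert-average rule is specific to doubling)")
  d <- dim(vol$data)
  if (d[3] < 2L) stop("need at least 2 slices to interpolate between")
  zout <- 2L * d[3] - 1L
  out <- array(0, dim = c(d[1], d[2], zout))
  out[, , seq(1L, zout, by = 2L)] <- vol$data
  out[, , seq(2L, zout - 1L, by = 2L)] <-
    (vol$data[, , -d[3], drop = FALSE] + vol$data[, , -1L, drop = FALSE]) / 2
  if (pad_last_slice) {
    out <- array(c(out, out[, , zout]), dim = c(d[1], d[2], zout + 1L))
  }
  volume_grid(out, spacing = c(1, 1, 1))
}

#' Reslice a binary mask by nearest neighbour
#'
#' Masks must stay binary, so the insert-average rule does not apply;
#' inserted slices copy the nearer original slice (ties resolved to the
#' slice below, i.e. the lower z index).
#'
#' @param mask binary [volume_grid] at (1, 1, 2) mm.
#' @inheritParams reslice_isotropic
#' @return binary isotropic [volume_grid].
#' @export
reslice_mask <- function(mask, pad_last_slice = FALSE) {
  stopifnot_volume(mask)
  d <- dim(mask$data)
  if (d[3] < 2L) stop("need at least 2 slices")
  zout <- 2L * d[3] - 1L
  out <- array(0, dim = c(d[1], d[2], zout))
  out[, , seq(1L, zout, by = 2L)] <- mask$data
  # inserted slice midway between originals: tie -> slice below
  out[, , seq(2L, zout - 1L, by = 2L)] <- mask$data[, , -d[3], drop = FALSE]
  if (pad_last_slice)
    out <- array(c(out, out[, , zout]), dim = c(d[1], d[2], zout + 1L))
  volume_grid((out != 0) * 1, spacing = c(1, 1, 1))
}

#' Apply a region-of-interest mask to a volume
#'
#' Voxels outside the ROI are set to `NA`, the sentinel excluded from all
#' downstream statistics and component extraction.
#'
#' @param vol a [volume_grid].
#' @param roi a binary [volume_grid] on the same grid.
#' @return masked [volume_grid].
#' @export
apply_roi <- function(vol, roi) {
  stopifnot_volume(vol); stopifnot_volume(roi)
  if (!identical(dim(vol$data), dim(roi$data)))
    stop("ROI shape ", paste(dim(roi$data), collapse = "x"),
         " does not match volume shape ", paste(dim(vol$data), collapse = "x"))
  out <- vol$data
  out[roi$data == 0] <- NA_real_
  volume_grid(out, vol$spacing)
}
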