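#' Construct a volume grid
#'
#' A `volume_grid` is the package's carrier for 3-D image data: a numeric
#' array plus per-axis voxel spacing in millimetres. Axis order is fixed as
#' (x, y, z) with z the slice (through-plane) axis, matching axial
#' T2-weighted acquisitions where in-plane resolution is finer than the
#' slice thickness.
#'
#' @param data 3-D numeric (or logical) array.
#' @param spacing numeric length-3 vector of voxel spacing in mm, all > 0.
#' @return An object of class `volume_grid` with elements `data` and
#'   `spacing`.
#' @export
#' @examples
#' v <- volume_grid(array(0, c(8, 8, 4)), spacing = c(1, 1, 2))
#' dim(v)
volume_grid <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (is.logical(data) || is.integer(data)) storage.mode(data) <- "double"
  if (!is.numeric(data)) stop("`data` must be numeric")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  structure(list(data = data, spacing = spacing), class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

is_volume_grid <- function(x) inherits(x, "volume_grid")

stopifnot_volume <- function(x, arg = deparse(substitute(x))) {
  if (!is_volume_grid(x)) stop(sprintf("`%s` must be a volume_grid", arg))
  invisible(x)
}
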