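#' Minimal NIfTI-1 input/output
#'
#' Self-contained reader/writer for single-file NIfTI-1 (`.nii`, `.nii.gz`)
#' volumes, sufficient for the pipeline's needs: a 3-D image with per-axis
#' voxel spacing encoded in `pixdim` and a diagonal sform. No general NIfTI
#' package is assumed to be available, so only the subset of the format this
#' pipeline produces and consumes is supported (datatypes uint8, int16,
#' int32, float32, float64; no extensions; no non-diagonal orientation).
#'
#' @param vol a [volume_grid].
#' @param path output file; `.gz` suffix triggers gzip compression.
#' @param datatype one of `"float32"`, `"float64"`, `"uint8"`, `"int16"`,
#'   `"int32"`.
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns a
#'   [volume_grid].
#' @name nifti_io
NULL

.nifti_dt <- list(uint8 = c(code = 2L, bitpix = 8L),
                  int16 = c(code = 4L, bitpix = 16L),
                  int32 = c(code = 8L, bitpix = 32L),
                  float32 = c(code = 16L, bitpix = 32L),
                  float64 = c(code = 64L, bitpix = 64L))

#' @rdname nifti_io
#' @export
write_nifti <- function(vol, path, datatype = "float32") {
  stopifnot_volume(vol)
  dt <- .nifti_dt[[match.arg(datatype, names(.nifti_dt))]]
  d <- dim(vol$data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x, size = 4) writeBin(as.numeric(x), con, size = size, endian = "little")
  wc <- function(s, len) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(len - length(raw_s))), con)
  }
  wi(348L, 4)                              # sizeof_hdr
  wc("", 10); wc("", 18); wi(0L, 4); wi(0L, 2); wc("", 1); wc("", 1)
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)          # dim[8]
  wf(c(0, 0, 0), 4)                        # intent_p1..p3
  wi(0L, 2)                                # intent_code
  wi(dt["code"], 2); wi(dt["bitpix"], 2)   # datatype, bitpix
  wi(0L, 2)                                # slice_start
  wf(c(1, vol$spacing, 1, 1, 1, 1), 4)     # pixdim[8] (qfac = 1)
  wf(352, 4)                               # vox_offset
  wf(1, 4); wf(0, 4)                       # scl_slope, scl_inter
  wi(0L, 2); wi(0L, 1); wi(10L, 1)         # slice_end, slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0), 4)                     # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                         # glmax, glmin
  wc("pvsmorph", 80); wc("", 24)           # descrip, aux_file
  wi(0L, 2); wi(1L, 2)                     # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0), 4)               # quatern b,c,d + qoffset x,y,z
  wf(c(vol$spacing[1], 0, 0, 0), 4)        # srow_x
  wf(c(0, vol$spacing[2], 0, 0), 4)        # srow_y
  wf(c(0, 0, vol$spacing[3], 0), 4)        # srow_z
  wc("", 16); wc("n+1", 4)                 # intent_name, magic
  writeBin(raw(4), con)                    # extension flag
  x <- as.vector(vol$data)
  if (dt["code"] %in% c(2L, 4L, 8L)) {
    writeBin(as.integer(round(x)), con, size = dt["bitpix"] / 8L,
             endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = dt["bitpix"] / 8L, endian = "little")
  }
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")   # gzfile transparently reads uncompressed files
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)
  ri <- function(off, size, n = 1, endian = "little")
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian)
  rf <- function(off, n = 1, endian = "little")
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = endian)
  endian <- "little"
  if (ri(0, 4) != 348L) {
    if (ri(0, 4, endian = "big") == 348L) endian <- "big"
    else stop("not a NIfTI-1 file: ", path)
  }
  ri2 <- function(off, size, n = 1) ri(off, size, n, endian)
  rf2 <- function(off, n = 1) rf(off, n, endian)
  ndim <- ri2(40, 2)
  if (ndim < 3) stop("expected a 3-D NIfTI volume")
  d <- ri2(42, 2, 3)
  extra <- if (ndim > 3) ri2(48, 2, ndim - 3) else integer()
  if (any(extra > 1)) stop("only 3-D volumes are supported")
  datatype <- ri2(70, 2)
  pixdim <- rf2(76, 8)[2:4]
  vox_offset <- rf2(108)
  scl_slope <- rf2(112); scl_inter <- rf2(116)
  if (scl_slope == 0) scl_slope <- 1
  nvox <- prod(d)
  # skip to data
  readBin(con, "raw", n = vox_offset - 348)
  x <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n = nvox, size = 1,
                              signed = FALSE, endian = endian)),
    "4"  = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                              endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", n = nvox, size = 4,
                              endian = endian)),
    "16" = readBin(con, "double", n = nvox, size = 4, endian = endian),
    "64" = readBin(con, "double", n = nvox, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code ", datatype))
  if (length(x) < nvox) stop("truncated NIfTI data in ", path)
  x <- x * scl_slope + scl_inter
  volume_grid(array(x, dim = d), spacing = pixdim)
}
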