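# Minimal NIfTI-1 (.nii, single-file, uncompressed) reader and writer.
#
# The scope is deliberately narrow: regular voxel grids with per-axis spacing
# and a translation-only world transform, which is all the analysis here needs
# (velocity component axes are the grid axes; orientation matrices beyond
# spacing/origin are out of scope).  Supported datatypes: uint8, int16, int32,
# float32, float64.  Both endiannesses are read; files are written in the
# platform's native order.

.nifti_dt <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

.nifti_dt_by_code <- function(code) {
  for (nm in names(.nifti_dt)) {
    if (.nifti_dt[[nm]]$code == code) return(c(.nifti_dt[[nm]], list(name = nm)))
  }
  stop("unsupported NIfTI datatype code: ", code)
}

#' Read a NIfTI-1 volume
#'
#' Reads an uncompressed single-file NIfTI-1 volume (`.nii`).  Only regular
#' grids with a translation-only transform are interpreted; orientation is
#' ignored by design.
#'
#' @param path Path to a `.nii` file.
#' @return A list of class `nifti_volume` with elements `data` (numeric array,
#'   3-D or 4-D), `spacing` (per-axis voxel size, mm), `dt` (4th-dimension
#'   step, ms, or `NA`), `origin` (world offset of the first voxel corner, mm),
#'   and `datatype`.
#' @seealso [write_nifti()]
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  endian <- .Platform$endian
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- setdiff(c("little", "big"), endian)
    seek(con, 0L)
    sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  seek(con, 40L)
  dim <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  ndim <- dim[1L]
  if (ndim < 3L || ndim > 4L) stop("only 3-D/4-D volumes supported, got ndim = ", ndim)
  shape <- dim[2L:(1L + ndim)]
  seek(con, 70L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  dt_info <- .nifti_dt_by_code(datatype)
  seek(con, 76L)
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  seek(con, 344L)
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic[1:3], charToRaw("n+1")))
    stop("not a single-file NIfTI-1 volume: ", path)
  seek(con, 280L)
  srow <- matrix(readBin(con, "double", 12L, size = 4L, endian = endian),
                 nrow = 3L, byrow = TRUE)

  seek(con, as.integer(vox_offset))
  n <- prod(shape)
  raw_vals <- readBin(con, dt_info$what, n, size = dt_info$size,
                      signed = dt_info$signed, endian = endian)
  if (length(raw_vals) != n) stop("truncated NIfTI data in ", path)
  if (is.na(scl_slope) || scl_slope == 0) scl_slope <- 1
  if (is.na(scl_inter)) scl_inter <- 0
  vals <- as.numeric(raw_vals) * scl_slope + scl_inter

  structure(list(
    data = array(vals, dim = shape),
    spacing = pixdim[2L:4L],
    dt = if (ndim == 4L) pixdim[5L] else NA_real_,
    origin = srow[, 4L],
    datatype = dt_info$name
  ), class = "nifti_volume")
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3-D or 4-D numeric array as an uncompressed single-file NIfTI-1
#' volume with the given per-axis spacing.  `NA` values are stored as NaN
#' (floating-point datatypes only).
#'
#' @param data Numeric or logical array, 3-D or 4-D.
#' @param path Output path (`.nii`).
#' @param spacing Per-axis voxel size in mm (length 3).
#' @param dt Step of the 4th dimension in ms (frame interval); ignored for 3-D.
#' @param origin World offset in mm of the grid (length 3, default 0).
#' @param datatype One of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing, dt = NA_real_,
                        origin = c(0, 0, 0), datatype = "float32") {
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L) stop("data must be a 3-D or 4-D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  dt_info <- .nifti_dt[[datatype]]
  if (is.null(dt_info)) stop("unsupported datatype: ", datatype)
  if (dt_info$what == "integer" && anyNA(data))
    stop("NA values require a floating-point datatype")

  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))

  dim8 <- integer(8L)
  dim8[1L] <- nd
  dim8[2L:(1L + nd)] <- dim(data)
  dim8[(2L + nd):8L] <- 1L
  pixdim <- numeric(8L)
  pixdim[1L] <- 1
  pixdim[2L:4L] <- spacing
  pixdim[5L] <- if (nd == 4L && is.finite(dt)) dt else 0

  writeBin(348L, con, size = 4L)                       # sizeof_hdr
  writeBin(raw(36L), con)                              # data_type..dim_info
  writeBin(as.integer(dim8), con, size = 2L)           # dim[8]
  writeBin(numeric(3L), con, size = 4L)                # intent_p1..p3
  writeBin(0L, con, size = 2L)                         # intent_code
  writeBin(as.integer(dt_info$code), con, size = 2L)   # datatype
  writeBin(as.integer(dt_info$bitpix), con, size = 2L) # bitpix
  writeBin(0L, con, size = 2L)                         # slice_start
  writeBin(pixdim, con, size = 4L)                     # pixdim[8]
  writeBin(352, con, size = 4L)                        # vox_offset
  writeBin(c(1, 0), con, size = 4L)                    # scl_slope, scl_inter
  writeBin(0L, con, size = 2L)                         # slice_end
  writeBin(raw(2L), con)                               # slice_code, xyzt_units
  writeBin(numeric(3L), con, size = 4L)                # cal_max, cal_min, slice_duration
  writeBin(0, con, size = 4L)                          # toffset
  writeBin(c(0L, 0L), con, size = 4L)                  # glmax, glmin
  writeBin(raw(80L + 24L), con)                        # descrip, aux_file
  writeBin(c(0L, 1L), con, size = 2L)                  # qform_code=0, sform_code=1
  writeBin(numeric(6L), con, size = 4L)                # quatern b,c,d, qoffset x,y,z
  srow <- rbind(c(spacing[1L], 0, 0, origin[1L]),
                c(0, spacing[2L], 0, origin[2L]),
                c(0, 0, spacing[3L], origin[3L]))
  writeBin(as.numeric(t(srow)), con, size = 4L)        # srow_x, srow_y, srow_z
  writeBin(raw(16L), con)                              # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL)
  writeBin(as.raw(c(0L, 0L, 0L, 0L, 0L)), con)         # magic NUL + 4-byte pad

  vals <- as.vector(data)
  if (dt_info$what == "integer") {
    writeBin(as.integer(vals), con, size = dt_info$size)
  } else {
    writeBin(as.numeric(vals), con, size = dt_info$size)
  }
  invisible(path)
}
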