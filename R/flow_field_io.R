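# Containers and on-disk I/O for 4D flow velocity fields, segmentation masks
# and derived voxel maps.
#
# On-disk layout: one 4-D NIfTI volume (x, y, z, t) per velocity component,
# named <stem>_vx.nii / _vy.nii / _vz.nii, plus a JSON sidecar <stem>.json
# carrying spacing (mm), dt (ms), venc (cm/s), units and origin.  Velocity
# component axes are the grid axes; voxel centers sit at
# origin + (index + 0.5) * spacing with 0-based indices.

#' Construct a 4D velocity field
#'
#' Bundles the three velocity components measured by 4D flow MRI on a regular
#' voxel grid with the acquisition parameters needed downstream.
#'
#' @param vx,vy,vz 4-D numeric arrays `(nx, ny, nz, nt)`, velocity in m/s
#'   along the three grid axes.  A 3-D array is promoted to a single frame.
#' @param spacing Per-axis voxel size in mm (length 3, all > 0).
#' @param dt Frame interval in ms (> 0).
#' @param venc Velocity-encoding limit in cm/s, length 1 or 3 (per component).
#' @param origin World offset of the grid in mm (length 3).
#' @return An object of class `velocity_field`.
#' @examples
#' f <- velocity_field(array(0.1, c(4, 4, 4, 2)), array(0, c(4, 4, 4, 2)),
#'                     array(0, c(4, 4, 4, 2)), spacing = c(2.5, 2.5, 2.5),
#'                     dt = 40, venc = 150)
#' dim(f$vx)
#' @export
velocity_field <- function(vx, vy, vz, spacing, dt, venc = 150,
                           origin = c(0, 0, 0)) {
  promote <- function(a) if (length(dim(a)) == 3L) array(a, c(dim(a), 1L)) else a
  vx <- promote(vx); vy <- promote(vy); vz <- promote(vz)
  if (!identical(dim(vx), dim(vy)) || !identical(dim(vx), dim(vz)))
    stop("velocity components must share an identical grid shape and frame count")
  if (length(dim(vx)) != 4L) stop("components must be 4-D (nx, ny, nz, nt) arrays")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive frame interval (ms)")
  venc <- as.numeric(venc)
  if (length(venc) == 1L) venc <- rep(venc, 3L)
  if (length(venc) != 3L || any(!is.finite(venc)) || any(venc <= 0))
    stop("venc must be positive (cm/s), length 1 or 3")
  structure(list(vx = vx, vy = vy, vz = vz, spacing = spacing,
                 dt = dt, venc = venc, origin = as.numeric(origin)),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$vx)
  cat(sprintf("<velocity_field> grid %d x %d x %d, %d frame(s)\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %.3g x %.3g x %.3g mm, dt %.3g ms, venc %s cm/s\n",
              x$spacing[1], x$spacing[2], x$spacing[3], x$dt,
              paste(signif(x$venc, 3), collapse = "/")))
  invisible(x)
}

#' Construct a segmentation mask
#'
#' @param voxels Logical (or 0/1 numeric) 3-D array aligned to the field grid.
#' @param label Role of the mask: `"whole-aorta"` or `"AAo-ROI"`.
#' @param field Optional `velocity_field`; when given, the spatial shape is
#'   validated against it.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(voxels, label = c("whole-aorta", "AAo-ROI"),
                              field = NULL) {
  label <- match.arg(label)
  if (is.numeric(voxels)) voxels <- array(voxels > 0, dim = dim(voxels))
  if (!is.logical(voxels) || length(dim(voxels)) != 3L)
    stop("mask voxels must be a logical 3-D array")
  if (anyNA(voxels)) stop("mask contains NA voxels")
  if (!any(voxels)) stop("empty mask: no voxel is set")
  if (!is.null(field) && !identical(dim(voxels), dim(field$vx)[1:3]))
    stop(sprintf("mask grid %s does not match field grid %s",
                 paste(dim(voxels), collapse = "x"),
                 paste(dim(field$vx)[1:3], collapse = "x")))
  structure(list(voxels = voxels, label = label), class = "segmentation_mask")
}

#' Analysis configuration
#'
#' Holds the physical and numerical parameters of the voxelwise analysis.
#'
#' @param mu Dynamic blood viscosity in Pa.s.  Default 3.2e-3, the standard
#'   value assumed for blood in the 4D flow literature.
#' @param boundary_policy Gradient scheme at mask edges. `"one_sided"`
#'   (default) falls back to one-sided differences where only one axis
#'   neighbor is in-mask; `"central_only"` leaves such voxels undefined.
#' @param include_divergence_term If `TRUE`, subtract the compressibility
#'   correction (2/3) mu (div v)^2 from the dissipation; both forms coincide
#'   on divergence-free fields.
#' @param seed Integer RNG seed used by stochastic steps (pathline seeding).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(mu = 3.2e-3,
                            boundary_policy = c("one_sided", "central_only"),
                            include_divergence_term = FALSE, seed = 1L) {
  boundary_policy <- match.arg(boundary_policy)
  if (!is.finite(mu) || mu <= 0) stop("mu must be a positive viscosity (Pa.s)")
  structure(list(mu = mu, boundary_policy = boundary_policy,
                 include_divergence_term = isTRUE(include_divergence_term),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# ---- on-disk I/O -----------------------------------------------------------

#' Read a 4D velocity field from a component-per-file dataset
#'
#' Expects three 4-D NIfTI volumes holding the vx/vy/vz components and a
#' metadata list (typically from the JSON sidecar, see
#' [read_velocity_dataset()]).  Velocities are converted to m/s on load
#' regardless of the unit declared in the metadata.
#'
#' @param component_paths Named or positional character vector of three paths,
#'   in vx, vy, vz order.
#' @param meta List with `spacing` (mm), `dt` (ms), `venc` (cm/s), optional
#'   `velocity_unit` (`"m/s"` or `"cm/s"`, default `"m/s"`) and `origin` (mm).
#' @return A [velocity_field()].
#' @export
read_velocity_field <- function(component_paths, meta) {
  if (length(component_paths) != 3L) stop("exactly three component paths required")
  for (fld in c("spacing", "dt")) {
    if (is.null(meta[[fld]])) stop("metadata missing required field: ", fld)
  }
  vols <- lapply(component_paths, read_nifti)
  dims <- lapply(vols, function(v) dim(v$data))
  if (!identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]]))
    stop(sprintf("component dimension mismatch: vx %s, vy %s, vz %s",
                 paste(dims[[1]], collapse = "x"), paste(dims[[2]], collapse = "x"),
                 paste(dims[[3]], collapse = "x")))
  unit <- if (is.null(meta$velocity_unit)) "m/s" else meta$velocity_unit
  scale <- switch(unit, "m/s" = 1, "cm/s" = 0.01, "mm/s" = 0.001,
                  stop("unknown velocity unit: ", unit))
  grab <- function(v) {
    a <- v$data * scale
    if (length(dim(a)) == 3L) array(a, c(dim(a), 1L)) else a
  }
  venc <- if (is.null(meta$venc)) 150 else meta$venc
  origin <- if (is.null(meta$origin)) vols[[1]]$origin else meta$origin
  velocity_field(grab(vols[[1]]), grab(vols[[2]]), grab(vols[[3]]),
                 spacing = meta$spacing, dt = meta$dt, venc = venc,
                 origin = origin)
}

#' Read a dataset by stem (components + JSON sidecar)
#'
#' @param stem Path prefix: `<stem>_vx.nii`, `<stem>_vy.nii`, `<stem>_vz.nii`
#'   and `<stem>.json` must exist.
#' @return A [velocity_field()].
#' @export
read_velocity_dataset <- function(stem) {
  sidecar <- paste0(stem, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar metadata: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  read_velocity_field(paste0(stem, c("_vx.nii", "_vy.nii", "_vz.nii")), meta)
}

#' Write a velocity field as a component-per-file dataset
#'
#' Writes `<stem>_vx.nii`, `_vy.nii`, `_vz.nii` (float32, m/s) and the JSON
#' sidecar `<stem>.json`.
#'
#' @param field A [velocity_field()].
#' @param stem Output path prefix.
#' @return `stem`, invisibly.
#' @export
write_velocity_dataset <- function(field, stem) {
  stopifnot(inherits(field, "velocity_field"))
  for (comp in c("vx", "vy", "vz")) {
    write_nifti(field[[comp]], paste0(stem, "_", comp, ".nii"),
                spacing = field$spacing, dt = field$dt,
                origin = field$origin, datatype = "float32")
  }
  meta <- list(spacing = field$spacing, dt = field$dt, venc = field$venc,
               origin = field$origin, velocity_unit = "m/s")
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(stem)
}

#' Read a segmentation mask volume
#'
#' Binarizes an integer/boolean NIfTI volume (> 0 is in-mask) and validates
#' its shape against the velocity field grid.
#'
#' @param path Path to the mask volume.
#' @param field A [velocity_field()] the mask annotates.
#' @param label Mask role tag, see [segmentation_mask()].
#' @return A [segmentation_mask()].
#' @export
read_mask <- function(path, field, label = "whole-aorta") {
  vol <- read_nifti(path)
  if (length(dim(vol$data)) == 4L) {
    if (dim(vol$data)[4L] != 1L) stop("mask volume must be 3-D: ", path)
    vol$data <- array(vol$data, dim(vol$data)[1:3])
  }
  vals <- vol$data
  if (any(abs(vals - round(vals)) > 1e-6))
    stop("mask volume is not integer/boolean valued: ", path)
  segmentation_mask(vals > 0, label = label, field = field)
}

#' Write a segmentation mask volume
#'
#' @param mask A [segmentation_mask()].
#' @param path Output `.nii` path.
#' @param spacing Per-axis voxel size in mm.
#' @param origin World offset in mm.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing, origin = c(0, 0, 0)) {
  stopifnot(inherits(mask, "segmentation_mask"))
  write_nifti(array(as.integer(mask$voxels), dim(mask$voxels)), path,
              spacing = spacing, origin = origin, datatype = "uint8")
}

#' Write a voxel scalar map
#'
#' Stores a per-voxel scalar map (e.g. a VELR or vorticity-magnitude map) as a
#' float32 NIfTI volume.  `NA` values outside the defined region are stored as
#' NaN and restored as `NA` on read.
#'
#' @param map A `voxel_scalar_map` (see [compute_velr_map()]) or a plain 3-D
#'   numeric array.
#' @param path Output `.nii` path.
#' @param spacing Per-axis voxel size in mm; taken from the map when present.
#' @param origin World offset in mm.
#' @return `path`, invisibly.
#' @export
write_voxel_map <- function(map, path, spacing = NULL, origin = c(0, 0, 0)) {
  if (inherits(map, "voxel_scalar_map")) {
    if (is.null(spacing)) spacing <- map$spacing
    values <- map$values
  } else {
    values <- map
  }
  if (is.null(spacing)) stop("spacing required to write a voxel map")
  write_nifti(values, path, spacing = spacing, origin = origin,
              datatype = "float32")
}

#' Read a voxel scalar map
#'
#' @param path Path to a `.nii` scalar map written by [write_voxel_map()].
#' @param quantity Quantity tag to attach, see [voxel_scalar_map()].
#' @param frame Frame index the map belongs to.
#' @return A [voxel_scalar_map()].
#' @export
read_voxel_map <- function(path, quantity = "velr_density", frame = 1L) {
  vol <- read_nifti(path)
  vals <- vol$data
  vals[is.nan(vals)] <- NA_real_
  voxel_scalar_map(vals, quantity = quantity, frame = frame,
                   spacing = vol$spacing)
}

# ---- velocity anti-aliasing ------------------------------------------------

#' Correct velocity aliasing (phase wraps)
#'
#' Phase-contrast velocities beyond the encoding limit (venc) alias by
#' 2 * venc.  For each voxel and component, the temporal median across frames
#' serves as the unwrapped reference: any frame value differing from the
#' median by more than venc is shifted by +/- 2 * venc toward it.  At most one
#' wrap is corrected per voxel-frame, so velocities beyond 3 * venc in
#' magnitude are not recoverable (multi-wrap correction is out of scope).
#' Output values lie within `(median - venc, median + venc]`; the operation is
#' idempotent on already-unwrapped data.
#'
#' @param field A [velocity_field()] with venc set per component (cm/s).
#' @return The corrected [velocity_field()].
#' @export
unwrap_velocity <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  nt <- dim(field$vx)[4L]
  for (ci in 1:3) {
    comp <- c("vx", "vy", "vz")[ci]
    venc_ms <- field$venc[ci] / 100                 # cm/s -> m/s
    v <- field[[comp]]
    med <- apply(v, 1:3, stats::median)
    medrep <- array(rep(med, times = nt), dim = dim(v))
    d <- v - medrep
    v[d > venc_ms] <- v[d > venc_ms] - 2 * venc_ms
    v[d <= -venc_ms] <- v[d <= -venc_ms] + 2 * venc_ms
    field[[comp]] <- v
  }
  field
}

#' Validate a dataset and summarize its grid
#'
#' Loads a `<stem>` dataset, checking component shapes and metadata, and
#' returns a one-line summary (used by the `load-check` CLI subcommand).
#'
#' @param stem Dataset path prefix.
#' @return A list with `field` and `summary` (character).
#' @export
load_check <- function(stem) {
  field <- read_velocity_dataset(stem)
  d <- dim(field$vx)
  summary <- sprintf(
    "grid %dx%dx%d, %d frames; spacing %.2fx%.2fx%.2f mm; dt %.1f ms; venc %s cm/s",
    d[1], d[2], d[3], d[4], field$spacing[1], field$spacing[2], field$spacing[3],
    field$dt, paste(signif(field$venc, 4), collapse = "/"))
  list(field = field, summary = summary)
}
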