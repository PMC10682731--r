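# Voxelwise hemodynamic quantification: peak-systole detection, the velocity
# gradient tensor by mask-aware finite differences, viscous energy loss rate
# (VELR) and vorticity maps, and ascending-aorta ROI summaries.

#' Voxel scalar map
#'
#' Per-voxel scalar quantity at one cardiac frame; `NA` outside the region
#' where the quantity is defined.
#'
#' @param values 3-D numeric array.
#' @param quantity One of `"velr_density"` (W/m^3), `"vorticity_magnitude"`
#'   (1/s), `"velocity_magnitude"` (m/s).
#' @param frame Frame index (1-based).
#' @param spacing Per-axis voxel size in mm (carried for I/O and summaries).
#' @return An object of class `voxel_scalar_map`.
#' @export
voxel_scalar_map <- function(values,
                             quantity = c("velr_density", "vorticity_magnitude",
                                          "velocity_magnitude"),
                             frame = 1L, spacing = NULL) {
  quantity <- match.arg(quantity)
  if (length(dim(values)) != 3L) stop("map values must be a 3-D array")
  if (quantity == "velr_density" && any(values < 0, na.rm = TRUE))
    stop("velr_density map must be nonnegative wherever defined")
  structure(list(values = values, quantity = quantity, frame = as.integer(frame),
                 spacing = spacing),
            class = "voxel_scalar_map")
}

#' Voxel vector map
#'
#' Per-voxel 3-component vector (vorticity, 1/s) at one frame.
#'
#' @param values 4-D numeric array `(nx, ny, nz, 3)`.
#' @param quantity Quantity tag (default `"vorticity"`).
#' @param frame Frame index.
#' @param spacing Per-axis voxel size in mm.
#' @return An object of class `voxel_vector_map`.
#' @export
voxel_vector_map <- function(values, quantity = "vorticity", frame = 1L,
                             spacing = NULL) {
  if (length(dim(values)) != 4L || dim(values)[4L] != 3L)
    stop("vector map values must be (nx, ny, nz, 3)")
  structure(list(values = values, quantity = quantity, frame = as.integer(frame),
                 spacing = spacing),
            class = "voxel_vector_map")
}

#' Magnitude of a voxel vector map
#'
#' @param vmap A [voxel_vector_map()].
#' @return A [voxel_scalar_map()] of the Euclidean norm per voxel.
#' @export
vector_map_magnitude <- function(vmap) {
  stopifnot(inherits(vmap, "voxel_vector_map"))
  mag <- sqrt(vmap$values[, , , 1]^2 + vmap$values[, , , 2]^2 +
                vmap$values[, , , 3]^2)
  voxel_scalar_map(mag, quantity = "vorticity_magnitude", frame = vmap$frame,
                   spacing = vmap$spacing)
}

#' Detect the peak systolic frame
#'
#' Peak systole is the cardiac frame at which the mean velocity magnitude of
#' the blood within the aortic segmentation is maximal; ties break to the
#' earliest frame.
#'
#' @param field A [velocity_field()].
#' @param mask A [segmentation_mask()] (whole aorta).
#' @return Frame index (1-based integer).
#' @export
detect_peak_systole <- function(field, mask) {
  stopifnot(inherits(field, "velocity_field"), inherits(mask, "segmentation_mask"))
  if (!identical(dim(mask$voxels), dim(field$vx)[1:3]))
    stop("mask grid does not match field grid")
  nt <- dim(field$vx)[4L]
  idx <- which(mask$voxels)
  nvox <- prod(dim(field$vx)[1:3])
  mean_speed <- vapply(seq_len(nt), function(t) {
    off <- (t - 1L) * nvox
    mean(sqrt(field$vx[idx + off]^2 + field$vy[idx + off]^2 +
                field$vz[idx + off]^2))
  }, numeric(1))
  which.max(mean_speed)           # which.max returns the first maximum
}

# Shift a 3-D array by one voxel along an axis; vacated slab is filled with
# `fill`.  by = +1 brings the value of the (i-1) neighbor to position i.
.shift3 <- function(a, axis, by, fill = NA) {
  out <- array(fill, dim = dim(a))
  n <- dim(a)[axis]
  if (n < 2L) return(out)
  if (axis == 1L) {
    if (by > 0) out[2:n, , ] <- a[1:(n - 1), , ] else out[1:(n - 1), , ] <- a[2:n, , ]
  } else if (axis == 2L) {
    if (by > 0) out[, 2:n, ] <- a[, 1:(n - 1), ] else out[, 1:(n - 1), ] <- a[, 2:n, ]
  } else {
    if (by > 0) out[, , 2:n] <- a[, , 1:(n - 1)] else out[, , 1:(n - 1)] <- a[, , 2:n]
  }
  out
}

# Mask-aware partial derivative of one 3-D component along one axis.
# Central differences where both axis neighbors are in-mask, one-sided where
# exactly one is (unless policy forbids it), NA otherwise.  h in meters.
.mask_deriv <- function(v, mask, axis, h, policy = "one_sided") {
  vp <- .shift3(v, axis, -1)                      # value at index + 1
  vm <- .shift3(v, axis, +1)                      # value at index - 1
  mp <- .shift3(mask, axis, -1, fill = FALSE)     # neighbor + in mask
  mm <- .shift3(mask, axis, +1, fill = FALSE)
  d <- array(NA_real_, dim = dim(v))
  ctr <- mask & mp & mm
  d[ctr] <- (vp[ctr] - vm[ctr]) / (2 * h)
  if (policy == "one_sided") {
    fwd <- mask & mp & !mm
    bwd <- mask & !mp & mm
    d[fwd] <- (vp[fwd] - v[fwd]) / h
    d[bwd] <- (v[bwd] - vm[bwd]) / h
  }
  d
}

#' Velocity gradient tensor at one frame
#'
#' Computes the per-voxel tensor G\[i, j\] = dv_i / dx_j (1/s) by finite
#' differences restricted to the segmentation: central differences where both
#' axis neighbors are in-mask, one-sided where exactly one is (under the
#' default `"one_sided"` boundary policy), undefined (`NA`) where neither is.
#' Spacing is converted mm to m so the tensor is in 1/s.
#'
#' @param field A [velocity_field()].
#' @param frame Frame index (1-based).
#' @param mask A [segmentation_mask()].
#' @param boundary_policy `"one_sided"` or `"central_only"`.
#' @return 5-D array `(nx, ny, nz, 3, 3)` of class `velocity_gradient`, with
#'   spacing (mm) attached as attribute `spacing`.
#' @export
velocity_gradient <- function(field, frame, mask,
                              boundary_policy = c("one_sided", "central_only")) {
  boundary_policy <- match.arg(boundary_policy)
  stopifnot(inherits(field, "velocity_field"), inherits(mask, "segmentation_mask"))
  nt <- dim(field$vx)[4L]
  if (frame < 1L || frame > nt) stop("frame out of range: ", frame)
  if (!identical(dim(mask$voxels), dim(field$vx)[1:3]))
    stop("mask grid does not match field grid")
  sh <- dim(field$vx)[1:3]
  h_m <- field$spacing / 1000
  G <- array(NA_real_, dim = c(sh, 3L, 3L))
  comps <- list(field$vx[, , , frame, drop = TRUE],
                field$vy[, , , frame, drop = TRUE],
                field$vz[, , , frame, drop = TRUE])
  for (i in 1:3) {
    vi <- array(comps[[i]], dim = sh)
    for (j in 1:3) {
      G[, , , i, j] <- .mask_deriv(vi, mask$voxels, j, h_m[j], boundary_policy)
    }
  }
  structure(G, class = "velocity_gradient", spacing = field$spacing,
            frame = as.integer(frame))
}

#' Viscous energy loss rate map
#'
#' The voxelwise viscous dissipation rate of kinetic energy (W/m^3): with
#' strain-rate tensor S = (G + G^T) / 2,
#' \deqn{\mathrm{VELR} = 2 \mu \sum_{ij} S_{ij}^2}
#' optionally minus the compressibility correction
#' \eqn{(2/3)\mu(\mathrm{tr}\,G)^2}; the two forms coincide on
#' divergence-free flow.  Results are clamped at 0 (the correction can push
#' discretized values marginally negative).
#'
#' @param grad A [velocity_gradient()] tensor.
#' @param config An [analysis_config()] supplying the viscosity `mu` and the
#'   `include_divergence_term` flag.
#' @return A [voxel_scalar_map()] with quantity `"velr_density"`, `NA` where
#'   the gradient is undefined.
#' @export
compute_velr_map <- function(grad, config = analysis_config()) {
  stopifnot(inherits(grad, "velocity_gradient"), inherits(config, "analysis_config"))
  mu <- config$mu
  # 2 mu sum_ij S_ij^2 = 2 mu sum_i G_ii^2 + mu sum_{i<j} (G_ij + G_ji)^2
  velr <- 2 * mu * (grad[, , , 1, 1]^2 + grad[, , , 2, 2]^2 + grad[, , , 3, 3]^2) +
    mu * ((grad[, , , 1, 2] + grad[, , , 2, 1])^2 +
            (grad[, , , 1, 3] + grad[, , , 3, 1])^2 +
            (grad[, , , 2, 3] + grad[, , , 3, 2])^2)
  if (config$include_divergence_term) {
    div <- grad[, , , 1, 1] + grad[, , , 2, 2] + grad[, , , 3, 3]
    velr <- velr - (2 / 3) * mu * div^2
  }
  velr <- pmax(velr, 0)
  voxel_scalar_map(velr, quantity = "velr_density",
                   frame = attr(grad, "frame"), spacing = attr(grad, "spacing"))
}

#' Vorticity map
#'
#' The curl of the velocity field per voxel,
#' omega = (G32 - G23, G13 - G31, G21 - G12) in 1/s, where G\[i, j\] is the
#' velocity gradient tensor.  Its magnitude is twice the local angular
#' velocity of a fluid element in rigid rotation.
#'
#' @param grad A [velocity_gradient()] tensor.
#' @return A [voxel_vector_map()], `NA` where the gradient is undefined.
#' @export
compute_vorticity_map <- function(grad) {
  stopifnot(inherits(grad, "velocity_gradient"))
  sh <- dim(grad)[1:3]
  w <- array(NA_real_, dim = c(sh, 3L))
  w[, , , 1] <- grad[, , , 3, 2] - grad[, , , 2, 3]
  w[, , , 2] <- grad[, , , 1, 3] - grad[, , , 3, 1]
  w[, , , 3] <- grad[, , , 2, 1] - grad[, , , 1, 2]
  voxel_vector_map(w, quantity = "vorticity", frame = attr(grad, "frame"),
                   spacing = attr(grad, "spacing"))
}

#' Summarize VELR and vorticity over a region of interest
#'
#' Computes the ascending-aorta summary metrics: total VELR (the voxelwise
#' VELR integrated over the ROI, reported in mW), VELR density (total VELR
#' divided by ROI volume, W/m^3), and mean vorticity (the ROI integral of
#' vorticity magnitude divided by ROI volume, 1/s; on a uniform grid this is
#' the plain voxel average of the magnitude).
#'
#' Voxels inside the ROI where a map is undefined (isolated voxels under the
#' `"central_only"` policy) contribute nothing to the sums but do count
#' toward the ROI volume.
#'
#' @param velr A [voxel_scalar_map()] with quantity `"velr_density"`.
#' @param vort A [voxel_vector_map()] (or its magnitude scalar map).
#' @param roi A [segmentation_mask()] delimiting the ROI.
#' @param spacing Per-axis voxel size in mm; defaults to the map spacing.
#' @return A list of class `hemodynamic_summary`: `peak_frame`,
#'   `total_velr_mW`, `velr_density_W_m3`, `mean_vorticity_s1`,
#'   `roi_volume_m3`.
#' @export
summarize_roi <- function(velr, vort, roi, spacing = NULL) {
  stopifnot(inherits(velr, "voxel_scalar_map"), inherits(roi, "segmentation_mask"))
  if (inherits(vort, "voxel_vector_map")) vort <- vector_map_magnitude(vort)
  if (is.null(spacing)) spacing <- velr$spacing
  if (is.null(spacing)) stop("spacing unavailable: supply it explicitly")
  if (!identical(dim(velr$values), dim(roi$voxels)) ||
      !identical(dim(vort$values), dim(roi$voxels)))
    stop("maps and ROI must share the same grid")
  in_roi <- roi$voxels
  if (!any(in_roi)) stop("empty ROI")
  dV <- prod(spacing / 1000)                      # voxel volume, m^3
  roi_volume <- sum(in_roi) * dV
  total_velr_W <- sum(velr$values[in_roi], na.rm = TRUE) * dV
  mean_vort <- sum(vort$values[in_roi], na.rm = TRUE) * dV / roi_volume
  structure(list(peak_frame = velr$frame,
                 total_velr_mW = total_velr_W * 1000,
                 velr_density_W_m3 = total_velr_W / roi_volume,
                 mean_vorticity_s1 = mean_vort,
                 roi_volume_m3 = roi_volume),
            class = "hemodynamic_summary")
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat(sprintf(paste0("<hemodynamic_summary> frame %d\n",
                     "  total VELR     %.4g mW\n",
                     "  VELR density   %.4g W/m^3\n",
                     "  mean vorticity %.4g 1/s\n",
                     "  ROI volume     %.4g ml\n"),
              x$peak_frame, x$total_velr_mW, x$velr_density_W_m3,
              x$mean_vorticity_s1, x$roi_volume_m3 * 1e6))
  invisible(x)
}

#' Full peak-systole quantification of one dataset
#'
#' Convenience wrapper: detects peak systole in the whole-aorta mask, computes
#' the gradient tensor, VELR and vorticity maps at that frame, and summarizes
#' them over the ROI.
#'
#' @param field A [velocity_field()].
#' @param aorta_mask Whole-aorta [segmentation_mask()] (peak-systole search
#'   and gradient support).
#' @param roi_mask Ascending-aorta ROI [segmentation_mask()]; defaults to the
#'   whole-aorta mask.
#' @param config An [analysis_config()].
#' @return A list: `summary` (a `hemodynamic_summary`), `velr_map`,
#'   `vorticity_map`, `peak_frame`.
#' @export
quantify_hemodynamics <- function(field, aorta_mask, roi_mask = aorta_mask,
                                  config = analysis_config()) {
  if (!all(roi_mask$voxels <= aorta_mask$voxels))
    stop("ROI mask must be a subset of the whole-aorta mask")
  peak <- detect_peak_systole(field, aorta_mask)
  grad <- velocity_gradient(field, peak, aorta_mask,
                            boundary_policy = config$boundary_policy)
  velr <- compute_velr_map(grad, config)
  vort <- compute_vorticity_map(grad)
  summ <- summarize_roi(velr, vort, roi_mask)
  list(summary = summ, velr_map = velr, vorticity_map = vort, peak_frame = peak)
}

#' Erode a mask by one voxel (6-neighborhood)
#'
#' Keeps voxels whose six axis neighbors are all in-mask.  Used to restrict
#' quantitative phantom evaluations to the interior, where central
#' differences apply.
#'
#' @param mask A [segmentation_mask()].
#' @return The eroded [segmentation_mask()].
#' @export
erode_mask <- function(mask) {
  m <- mask$voxels
  keep <- m
  for (axis in 1:3) {
    keep <- keep & .shift3(m, axis, +1, fill = FALSE) &
      .shift3(m, axis, -1, fill = FALSE)
  }
  segmentation_mask(keep, label = mask$label)
}
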