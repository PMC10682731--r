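# Massless-particle pathline tracing through the time-resolved velocity
# field: 4th-order Runge-Kutta with trilinear spatial and linear temporal
# interpolation.  Positions are in mm, times in ms, velocities in m/s, so a
# displacement is simply v (m/s) * h (ms) mm.

# Sample the field at positions P (m x 3, mm) and time t (ms).  Returns an
# m x 3 velocity matrix (m/s).  Positions are clamped to the grid hull;
# termination is handled separately by .in_mask.
.sample_velocity <- function(field, P, t) {
  sh <- dim(field$vx)[1:3]
  nt <- dim(field$vx)[4L]
  if (nt == 1L) {
    k0 <- 1L; a <- 0
  } else {
    ft <- t / field$dt + 1
    k0 <- max(1L, min(nt - 1L, as.integer(floor(ft))))
    a <- min(1, max(0, ft - k0))
  }
  f <- sweep(sweep(P, 2L, field$origin, "-"), 2L, field$spacing, "/") + 0.5
  i0 <- matrix(0L, nrow(P), 3L)
  fr <- matrix(0, nrow(P), 3L)
  for (ax in 1:3) {
    fi <- pmin(pmax(f[, ax], 1), sh[ax])        # clamp to voxel-center hull
    i0[, ax] <- pmin(pmax(floor(fi), 1L), max(sh[ax] - 1L, 1L))
    fr[, ax] <- if (sh[ax] > 1L) fi - i0[, ax] else 0
  }
  nxy <- sh[1L] * sh[2L]
  nvox <- prod(sh)
  V <- matrix(0, nrow(P), 3L)
  for (comp in 1:3) {
    arr <- field[[c("vx", "vy", "vz")[comp]]]
    acc <- numeric(nrow(P))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
        (if (dy) fr[, 2] else 1 - fr[, 2]) *
        (if (dz) fr[, 3] else 1 - fr[, 3])
      if (all(w == 0)) next
      lin <- (i0[, 1] + dx) + (i0[, 2] + dy - 1L) * sh[1L] +
        (i0[, 3] + dz - 1L) * nxy
      val <- arr[lin + (k0 - 1L) * nvox]
      if (a > 0) val <- (1 - a) * val + a * arr[lin + k0 * nvox]
      acc <- acc + w * val
    }
    V[, comp] <- acc
  }
  V
}

# TRUE for particles whose nearest voxel is inside the mask (and the grid).
.in_mask <- function(mask_vox, spacing, origin, P) {
  sh <- dim(mask_vox)
  f <- sweep(sweep(P, 2L, origin, "-"), 2L, spacing, "/") + 0.5
  ni <- round(f)
  ok <- ni[, 1] >= 1 & ni[, 1] <= sh[1] & ni[, 2] >= 1 & ni[, 2] <= sh[2] &
    ni[, 3] >= 1 & ni[, 3] <= sh[3]
  inm <- ok
  if (any(ok)) {
    lin <- ni[ok, 1] + (ni[ok, 2] - 1) * sh[1] + (ni[ok, 3] - 1) * sh[1] * sh[2]
    inm[ok] <- mask_vox[lin]
  }
  inm
}

#' Trace pathlines through a time-resolved velocity field
#'
#' Massless particles are seeded uniformly at random inside the segmentation
#' at regular seeding epochs (every `seed_interval_ms`), and advected by
#' 4th-order Runge-Kutta with trilinear spatial and linear temporal velocity
#' interpolation.  A particle terminates when its nearest voxel leaves the
#' mask or the time axis ends.  Defaults follow the usual rendering protocol:
#' 400 particles in total, seeded at a 40 ms interval; the total count is
#' split as evenly as possible across the epochs.
#'
#' @param field A [velocity_field()] (a single-frame field is treated as
#'   steady).
#' @param mask A [segmentation_mask()] used for seeding and termination.
#' @param n_particles Total number of particles across all seeding epochs.
#' @param seed_interval_ms Interval between seeding epochs (ms).
#' @param rng_seed Integer seed for the seeding positions.
#' @param step_ms Integrator step (ms); defaults to `field$dt / 8`.
#' @param duration_ms Total traced time span (ms); defaults to the length of
#'   the time axis, `(nt - 1) * dt`.  Must be given a sensible value for
#'   steady single-frame fields.
#' @return An object of class `pathline_set`: a data.frame with columns
#'   `particle_id`, `t_ms`, `x_mm`, `y_mm`, `z_mm`, with attributes
#'   `seed_interval_ms`, `epochs_ms` and `particles_per_epoch`.
#' @export
trace_pathlines <- function(field, mask, n_particles = 400,
                            seed_interval_ms = 40, rng_seed = 1L,
                            step_ms = NULL, duration_ms = NULL) {
  stopifnot(inherits(field, "velocity_field"), inherits(mask, "segmentation_mask"))
  if (!any(mask$voxels)) stop("empty mask")
  if (!is.finite(seed_interval_ms) || seed_interval_ms <= 0)
    stop("seed_interval_ms must be positive")
  if (n_particles < 1) stop("n_particles must be at least 1")
  nt <- dim(field$vx)[4L]
  if (is.null(duration_ms)) duration_ms <- max((nt - 1L), 1L) * field$dt
  if (is.null(step_ms)) step_ms <- field$dt / 8
  if (step_ms <= 0 || duration_ms <= 0) stop("step and duration must be positive")

  # epochs strictly before the end of the time axis (an epoch at the very
  # end would seed particles with no time left to advect)
  epochs <- seed_interval_ms * seq(0, floor((duration_ms - 1e-6) / seed_interval_ms))
  k <- length(epochs)
  counts <- diff(floor(n_particles * (0:k) / k))
  mask_idx <- which(mask$voxels)
  sh <- dim(mask$voxels)

  set.seed(rng_seed)
  rows <- vector("list", 0L)
  next_id <- 1L
  for (ei in seq_len(k)) {
    m <- counts[ei]
    if (m == 0L) next
    vox <- mask_idx[sample.int(length(mask_idx), m, replace = TRUE)]
    ijk <- arrayInd(vox, sh)
    P <- sweep((ijk - 1 + matrix(stats::runif(3 * m), m, 3L)), 2L,
               field$spacing, "*")
    P <- sweep(P, 2L, field$origin, "+")
    ids <- next_id:(next_id + m - 1L)
    next_id <- next_id + m

    t <- epochs[ei]
    active <- rep(TRUE, m)
    rows[[length(rows) + 1L]] <- cbind(ids, t, P)
    while (t < duration_ms - 1e-9 && any(active)) {
      h <- min(step_ms, duration_ms - t)
      Pa <- P[active, , drop = FALSE]
      k1 <- .sample_velocity(field, Pa, t)
      k2 <- .sample_velocity(field, Pa + (h / 2) * k1, t + h / 2)
      k3 <- .sample_velocity(field, Pa + (h / 2) * k2, t + h / 2)
      k4 <- .sample_velocity(field, Pa + h * k3, t + h)
      Pa <- Pa + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
      P[active, ] <- Pa
      t <- t + h
      inside <- .in_mask(mask$voxels, field$spacing, field$origin, Pa)
      still <- which(active)[inside]
      active[] <- FALSE
      active[still] <- TRUE
      if (length(still)) {
        rows[[length(rows) + 1L]] <-
          cbind(still + ids[1L] - 1L, t, P[still, , drop = FALSE])
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- as.data.frame(out)
  names(out) <- c("particle_id", "t_ms", "x_mm", "y_mm", "z_mm")
  out <- out[order(out$particle_id, out$t_ms), ]
  rownames(out) <- NULL
  structure(out, seed_interval_ms = seed_interval_ms, epochs_ms = epochs,
            particles_per_epoch = counts,
            class = c("pathline_set", "data.frame"))
}
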