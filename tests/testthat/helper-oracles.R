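# Independent reference implementations used as oracles.  These are written
# naively (triple loops, scalar arithmetic) on purpose: they must not share
# code paths with the package internals they check.

# Brute-force velocity gradient: G[i,j] = dv_i/dx_j at every in-mask voxel,
# central/one-sided/undefined by neighbor availability.  spacing in mm.
brute_gradient <- function(field, frame, mask_vox, spacing_mm) {
  sh <- dim(mask_vox)
  h <- spacing_mm / 1000
  comps <- list(field$vx[, , , frame], field$vy[, , , frame],
                field$vz[, , , frame])
  G <- array(NA_real_, dim = c(sh, 3, 3))
  for (x in 1:sh[1]) for (y in 1:sh[2]) for (z in 1:sh[3]) {
    if (!mask_vox[x, y, z]) next
    idx <- c(x, y, z)
    for (j in 1:3) {
      up <- idx; up[j] <- up[j] + 1L
      dn <- idx; dn[j] <- dn[j] - 1L
      has_up <- up[j] <= sh[j] && mask_vox[up[1], up[2], up[3]]
      has_dn <- dn[j] >= 1L && mask_vox[dn[1], dn[2], dn[3]]
      for (i in 1:3) {
        v <- comps[[i]]
        g <- if (has_up && has_dn) {
          (v[up[1], up[2], up[3]] - v[dn[1], dn[2], dn[3]]) / (2 * h[j])
        } else if (has_up) {
          (v[up[1], up[2], up[3]] - v[x, y, z]) / h[j]
        } else if (has_dn) {
          (v[x, y, z] - v[dn[1], dn[2], dn[3]]) / h[j]
        } else NA_real_
        G[x, y, z, i, j] <- g
      }
    }
  }
  G
}

# Brute-force VELR from a gradient array: 2 mu sum_ij S_ij^2 per voxel.
brute_velr <- function(G, mu) {
  sh <- dim(G)[1:3]
  out <- array(NA_real_, sh)
  for (x in 1:sh[1]) for (y in 1:sh[2]) for (z in 1:sh[3]) {
    g <- matrix(G[x, y, z, , ], 3, 3)
    if (anyNA(g)) next
    S <- (g + t(g)) / 2
    out[x, y, z] <- 2 * mu * sum(S^2)
  }
  out
}

# Brute-force vorticity (curl) from a gradient array.
brute_vorticity <- function(G) {
  sh <- dim(G)[1:3]
  out <- array(NA_real_, c(sh, 3))
  for (x in 1:sh[1]) for (y in 1:sh[2]) for (z in 1:sh[3]) {
    g <- matrix(G[x, y, z, , ], 3, 3)
    out[x, y, z, ] <- c(g[3, 2] - g[2, 3], g[1, 3] - g[3, 1], g[2, 1] - g[1, 2])
  }
  out
}

# Voxel-center coordinate arrays (mm, grid-centered) matching the phantom
# generator's convention.
grid_coords <- function(shape, spacing) {
  axs <- lapply(1:3, function(a) ((seq_len(shape[a]) - 0.5) - shape[a] / 2) * spacing[a])
  list(
    X = array(rep(axs[[1]], times = shape[2] * shape[3]), shape),
    Y = array(rep(rep(axs[[2]], each = shape[1]), times = shape[3]), shape),
    Z = array(rep(axs[[3]], each = shape[1] * shape[2]), shape)
  )
}

# A small field builder for hand-made tests.
tiny_field <- function(fx, fy, fz, shape = c(8, 8, 8), spacing = c(3, 3, 3),
                       dt = 40, venc = 250) {
  co <- grid_coords(shape, spacing)
  mk <- function(f) array(f(co$X / 1000, co$Y / 1000, co$Z / 1000), c(shape, 1))
  velocity_field(mk(fx), mk(fy), mk(fz), spacing = spacing, dt = dt,
                 venc = venc, origin = -shape * spacing / 2)
}

full_mask <- function(shape = c(8, 8, 8)) {
  segmentation_mask(array(TRUE, shape))
}

# Plateau ejection waveform: sustained forward flow with a brief peak, kept
# high through most of the cycle so the temporal median of each voxel stays
# within venc of its peak velocity -- the regime in which the single-wrap
# median rule is guaranteed to invert synthetic aliasing (see the methods
# vignette).
plateau_waveform <- function(nt = 8) {
  w <- rep(0.75, nt)
  w[4] <- 1
  w[1] <- 0.5
  w[nt] <- 0.25
  w
}
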