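# Synthetic inputs with known ground truth: analytic voxel flow phantoms
# (with closed-form dissipation and vorticity), Doppler ejection traces with
# known VTI/TPG, and per-subject metric cohorts emulating the published
# group summaries.

#' Default systolic waveform
#'
#' Per-frame velocity scale factors: a half-sine systolic pulse occupying the
#' first half of the cycle, zero diastole.  The waveform peaks at a single
#' frame so the peak-systole detector has an unambiguous ground truth.
#'
#' @param nt Number of cardiac frames.
#' @return Numeric vector of length `nt` in `[0, 1]`.
#' @export
default_waveform <- function(nt) {
  if (nt == 1L) return(1)
  ns <- max(2L, floor(nt / 2))
  w <- numeric(nt)
  w[1:ns] <- sin(pi * (seq_len(ns) - 0.5) / ns)
  w
}

# Voxel-center coordinates (mm) relative to the grid center, per axis.
.grid_axes <- function(shape, spacing) {
  lapply(1:3, function(ax) {
    n <- shape[ax]
    ((seq_len(n) - 0.5) - n / 2) * spacing[ax]
  })
}

#' Generate an analytic flow phantom
#'
#' Samples a canonical analytic flow at the voxel centers of a regular grid,
#' applies a per-frame waveform, optional Gaussian velocity noise and
#' optional synthetic aliasing (wrapping into `(-venc, venc]`), and returns
#' the field together with its geometry mask and the closed-form ground
#' truth evaluated at the waveform peak.
#'
#' Families (axis along z, centered in the grid; lengths in mm, velocities
#' in m/s):
#' \describe{
#'   \item{`poiseuille`}{`vz = U (1 - r^2/R^2)` in a cylinder of radius `R`
#'     and length `L`.  Total dissipation over the cylinder is
#'     `2 pi mu L U^2`; mean vorticity magnitude is `(4/3) U / R`.}
#'   \item{`solid_rotation`}{rigid rotation at `omega0` rad/s inside a
#'     cylinder `R`, `L`: zero dissipation, vorticity magnitude `2 omega0`.}
#'   \item{`lamb_oseen`}{Lamb-Oseen vortex with circulation `gamma` (m^2/s)
#'     and core radius `r_c` inside a cylinder `R`, `L`;
#'     `omega_z(r) = gamma/(pi r_c^2) exp(-r^2/r_c^2)`.  The dissipation
#'     ground truth is obtained by 1-D quadrature of the analytic strain
#'     rate.}
#'   \item{`uniform`}{constant velocity `u` (length-3, m/s) on the full grid:
#'     zero dissipation and vorticity.}
#'   \item{`shear`}{linear shear `vx = k y` (`k` in 1/s) on the full grid:
#'     dissipation density `mu k^2`, vorticity magnitude `k`.}
#' }
#'
#' @param family One of `"poiseuille"`, `"solid_rotation"`, `"lamb_oseen"`,
#'   `"uniform"`, `"shear"`.
#' @param params Named list of family parameters (see Details): `R`, `L`
#'   (mm), `U` (m/s), `omega0` (rad/s), `gamma` (m^2/s), `r_c` (mm), `k`
#'   (1/s), `u` (length-3 m/s).
#' @param shape Grid dimensions (length 3).
#' @param spacing Voxel size in mm (length 3); default 2.5 mm isotropic,
#'   inside the clinical 4D flow acquisition range.
#' @param nt Number of frames (default 16).
#' @param dt Frame interval in ms (default 40, matching a ~39-41 ms temporal
#'   resolution).
#' @param waveform Per-frame scale factors (length `nt`); default
#'   [default_waveform()].
#' @param noise_sd Gaussian velocity noise SD in m/s (default 0).
#' @param venc Encoding velocity in cm/s (default 250, within the 150-275
#'   clinical range).
#' @param apply_wrap If `TRUE`, alias the stored velocities into
#'   `(-venc, venc]` (the pre-wrap field is retained in the ground truth).
#' @param rng_seed Seed for the noise.
#' @param mu Viscosity (Pa.s) used for the dissipation ground truth.
#' @return A list with `field` ([velocity_field()]), `mask`
#'   ([segmentation_mask()]) and `truth` (class `phantom_truth`): `family`,
#'   `params`, `mu`, `analytic_total_velr_W`, `analytic_velr_density_W_m3`,
#'   `analytic_mean_vorticity_s1`, `waveform`, `peak_frame`, and `prewrap`
#'   (the unwrapped [velocity_field()] when `apply_wrap`, else `NULL`).
#' @export
make_phantom <- function(family = c("poiseuille", "solid_rotation",
                                    "lamb_oseen", "uniform", "shear"),
                         params = list(), shape = c(64, 64, 64),
                         spacing = c(2.5, 2.5, 2.5), nt = 16L, dt = 40,
                         waveform = NULL, noise_sd = 0, venc = 250,
                         apply_wrap = FALSE, rng_seed = 1L, mu = 3.2e-3) {
  family <- match.arg(family)
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be nonnegative")
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L)) stop("shape must be 3 dims >= 2")
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (is.null(waveform)) waveform <- default_waveform(nt)
  if (length(waveform) != nt) stop("waveform length must equal nt")
  peak_frame <- which.max(waveform)
  wpk <- waveform[peak_frame]

  ax <- .grid_axes(shape, spacing)
  X <- array(rep(ax[[1]], times = shape[2] * shape[3]), dim = shape)
  Y <- array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), dim = shape)
  Z <- array(rep(ax[[3]], each = shape[1] * shape[2]), dim = shape)
  r2_mm <- X^2 + Y^2

  extent <- shape * spacing
  need_cyl <- function(R, L) {
    if (2 * R > extent[1] || 2 * R > extent[2] || L > extent[3])
      stop("phantom geometry exceeds the grid extent")
  }
  p <- params
  vx <- vy <- vz <- array(0, dim = shape)
  if (family == "poiseuille") {
    R <- p$R %||% 10; L <- p$L %||% 100; U <- p$U %||% 1
    need_cyl(R, L)
    # fluid at rest outside the conduit wall: clamp the parabola at 0 so the
    # stored field stays physical (gradients never cross the mask boundary,
    # so in-mask results are unaffected by the clamp)
    vz <- U * pmax(0, 1 - r2_mm / R^2)
    mask <- r2_mm <= R^2 & abs(Z) <= L / 2
    R_m <- R / 1000; L_m <- L / 1000
    total_velr <- 2 * pi * mu * L_m * (wpk * U)^2
    density <- total_velr / (pi * R_m^2 * L_m)
    mean_vort <- (4 / 3) * (wpk * U) / R_m
  } else if (family == "solid_rotation") {
    R <- p$R %||% 40; L <- p$L %||% 100; omega0 <- p$omega0 %||% 10
    need_cyl(R, L)
    vx <- -omega0 * Y / 1000                       # mm -> m
    vy <- omega0 * X / 1000
    mask <- r2_mm <= R^2 & abs(Z) <= L / 2
    total_velr <- 0
    density <- 0
    mean_vort <- 2 * omega0 * wpk
  } else if (family == "lamb_oseen") {
    R <- p$R %||% 40; L <- p$L %||% 100
    gamma <- p$gamma %||% 0.01; r_c <- p$r_c %||% 10
    need_cyl(R, L)
    r_m <- sqrt(r2_mm) / 1000
    rc_m <- r_c / 1000
    # v_theta(r) = gamma/(2 pi r) (1 - exp(-r^2/rc^2)); series-safe near 0
    vt <- ifelse(r_m > 1e-9,
                 gamma / (2 * pi * r_m) * (1 - exp(-(r_m / rc_m)^2)),
                 gamma * r_m / (2 * pi * rc_m^2))
    theta_x <- ifelse(r_m > 1e-9, -(Y / 1000) / r_m, 0)
    theta_y <- ifelse(r_m > 1e-9, (X / 1000) / r_m, 0)
    vx <- vt * theta_x
    vy <- vt * theta_y
    mask <- r2_mm <= R^2 & abs(Z) <= L / 2
    R_m <- R / 1000; L_m <- L / 1000; g <- gamma * wpk
    vth <- function(r) g / (2 * pi * r) * (1 - exp(-(r / rc_m)^2))
    dvth <- function(r) {
      e <- exp(-(r / rc_m)^2)
      -g / (2 * pi * r^2) * (1 - e) + g / (pi * rc_m^2) * e
    }
    # azimuthal strain: s = r d/dr (v/r) = dv/dr - v/r; VELR = mu s^2
    integrand <- function(r) mu * (dvth(r) - vth(r) / r)^2 * 2 * pi * r
    total_velr <- L_m * stats::integrate(integrand, 1e-9, R_m,
                                         rel.tol = 1e-10)$value
    density <- total_velr / (pi * R_m^2 * L_m)
    mean_vort <- g * (1 - exp(-(R_m / rc_m)^2)) / (pi * R_m^2)
  } else if (family == "uniform") {
    u <- p$u %||% c(0.5, 0, 0)
    vx <- array(u[1], shape); vy <- array(u[2], shape); vz <- array(u[3], shape)
    mask <- array(TRUE, shape)
    total_velr <- 0; density <- 0; mean_vort <- 0
  } else {                                         # shear
    k <- p$k %||% 5
    vx <- k * Y / 1000
    mask <- array(TRUE, shape)
    vol <- prod(extent / 1000)
    total_velr <- mu * (k * wpk)^2 * vol
    density <- mu * (k * wpk)^2
    mean_vort <- k * wpk
  }
  if (!any(mask)) stop("phantom geometry produced an empty mask")

  expand <- function(a) {
    out <- array(0, dim = c(shape, nt))
    for (t in seq_len(nt)) out[, , , t] <- a * waveform[t]
    out
  }
  VX <- expand(vx); VY <- expand(vy); VZ <- expand(vz)
  if (noise_sd > 0) {
    set.seed(rng_seed)
    n <- length(VX)
    VX <- VX + stats::rnorm(n, sd = noise_sd)
    VY <- VY + stats::rnorm(n, sd = noise_sd)
    VZ <- VZ + stats::rnorm(n, sd = noise_sd)
  }
  origin <- -shape * spacing / 2                   # grid centered on 0
  field <- velocity_field(VX, VY, VZ, spacing = spacing, dt = dt, venc = venc,
                          origin = origin)
  prewrap <- NULL
  if (apply_wrap) {
    prewrap <- field
    venc_ms <- field$venc / 100
    # leave in-band values untouched bitwise; alias the rest into (-venc, venc]
    wrap1 <- function(v, vc) {
      out <- v
      idx <- v > vc | v <= -vc
      out[idx] <- vc - ((vc - v[idx]) %% (2 * vc))
      out
    }
    field$vx <- wrap1(field$vx, venc_ms[1])
    field$vy <- wrap1(field$vy, venc_ms[2])
    field$vz <- wrap1(field$vz, venc_ms[3])
  }
  truth <- structure(list(
    family = family, params = p, mu = mu,
    analytic_total_velr_W = total_velr,
    analytic_velr_density_W_m3 = density,
    analytic_mean_vorticity_s1 = mean_vort,
    waveform = waveform, peak_frame = peak_frame,
    prewrap = prewrap
  ), class = "phantom_truth")
  list(field = field,
       mask = segmentation_mask(mask, label = "whole-aorta"),
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesize a Doppler ejection trace
#'
#' Builds a half-sine systolic pulse of known peak velocity repeated over
#' `n_cycles` cardiac cycles with zero diastole, and returns the closed-form
#' ground truth alongside: VTI = `2 tpv T / pi` (x100 cm), peak TPG =
#' `4 tpv^2`, mean TPG over the pulse = `2 tpv^2` (mean of sin^2 is 1/2).
#'
#' @param tpv Peak velocity in m/s.
#' @param pulse_width Systolic pulse width T in s.
#' @param cycle Cardiac cycle length in s (must exceed `pulse_width`).
#' @param n_cycles Number of cycles.
#' @param sampling Sampling rate in Hz.
#' @param modality,site Passed to [doppler_trace()].
#' @return A list with `trace` ([doppler_trace()]) and `truth` (list:
#'   `vti_cm`, `peak_tpg_mmHg`, `mean_tpg_mmHg`, `pulse_window_s` — the
#'   support of the first pulse).
#' @export
synthesize_doppler <- function(tpv, pulse_width = 0.3, cycle = 1.0,
                               n_cycles = 1L, sampling = 500,
                               modality = "CW", site = "aortic-valve") {
  if (!is.finite(tpv) || tpv < 0) stop("tpv must be nonnegative")
  if (pulse_width <= 0 || cycle <= pulse_width) stop("need 0 < pulse_width < cycle")
  if (sampling <= 0 || n_cycles < 1) stop("invalid timing parameters")
  t <- seq(0, n_cycles * cycle, by = 1 / sampling)
  phase <- t %% cycle
  v <- ifelse(phase < pulse_width, tpv * sin(pi * phase / pulse_width), 0)
  trace <- doppler_trace(t, v, modality = modality, site = site)
  truth <- list(vti_cm = 2 * tpv * pulse_width / pi * 100,
                peak_tpg_mmHg = 4 * tpv^2,
                mean_tpg_mmHg = 2 * tpv^2,
                pulse_window_s = c(0, pulse_width))
  list(trace = trace, truth = truth)
}

#' Default cohort group specifications
#'
#' The shipped defaults emulate the published three-group summaries
#' (bileaflet mechanical valved-conduit patients with an On-X prosthesis,
#' patients with St. Jude Medical or Carbomedics prostheses, and healthy
#' controls) at group sizes 10 / 6 / 36.  Metrics are mean and SD per group;
#' the healthy-control EOA, published as median (IQR), is approximated as a
#' normal with mean = median and SD = IQR / 1.349.
#'
#' @return A list of three group specs, each a list with `name`, `n` and
#'   `metrics` (a data.frame with `metric`, `mean`, `sd`).
#' @export
default_group_specs <- function() {
  metric_names <- c("tpv", "mean_tpg", "peak_tpg", "eoa", "eoai",
                    "total_velr", "velr_density", "mean_vorticity")
  spec <- function(name, n, means, sds) {
    list(name = name, n = n,
         metrics = data.frame(metric = metric_names, mean = means, sd = sds))
  }
  list(
    spec("On-X", 10L,
         means = c(1.9, 7.4, 15.3, 2.51, 1.21, 3.1, 50.6, 147.6),
         sds   = c(0.3, 1.9, 5.2, 0.58, 0.34, 1.0, 20.1, 30.0)),
    spec("SJM/CM", 6L,
         means = c(2.2, 9.2, 18.9, 2.53, 1.18, 6.0, 89.8, 191.2),
         sds   = c(0.3, 2.3, 5.2, 0.64, 0.30, 4.1, 35.2, 26.0)),
    spec("healthy", 36L,
         means = c(1.2, 3.1, 6.1, 2.3, 1.3, 1.6, 21.4, 84.6),
         sds   = c(0.2, 0.9, 1.8, 0.7 / 1.349, 0.30, 0.7, 9.2, 20.5))
  )
}

#' Simulate a per-subject metric cohort
#'
#' Draws each metric independently from a normal distribution with the
#' group's mean and SD, truncated at 0 by resampling (all shipped metrics
#' are physically nonnegative).  No inter-metric correlation is imposed:
#' only marginal summaries are published, so any correlation structure
#' would be invented.
#'
#' @param specs List of group specs as returned by [default_group_specs()].
#' @param rng_seed Integer seed; the same seed reproduces the same table.
#' @return A long-format data.frame of class `cohort_table` with columns
#'   `subject_id`, `group`, `metric`, `value`.
#' @export
simulate_cohort <- function(specs = default_group_specs(), rng_seed = 1L) {
  if (!length(specs)) stop("specs must be a nonempty list of group specs")
  for (s in specs) {
    if (is.null(s$n) || s$n < 2L) stop("each group needs n >= 2 subjects")
    if (any(s$metrics$sd < 0)) stop("SDs must be nonnegative")
  }
  set.seed(rng_seed)
  rtruncnorm0 <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    for (iter in 1:100) {
      bad <- x < 0
      if (!any(bad)) break
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    if (any(x < 0)) stop("truncation failed: group mean far below 0?")
    x
  }
  rows <- list()
  sid <- 0L
  for (s in specs) {
    ids <- sprintf("S%03d", sid + seq_len(s$n))
    sid <- sid + s$n
    for (mi in seq_len(nrow(s$metrics))) {
      m <- s$metrics[mi, ]
      vals <- if (m$sd == 0) rep(m$mean, s$n) else rtruncnorm0(s$n, m$mean, m$sd)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids, group = s$name, metric = m$metric, value = vals)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write / read a cohort table as CSV
#'
#' @param table A `cohort_table`.
#' @param path CSV path.
#' @return `path` invisibly; `read_cohort` returns the `cohort_table`.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "metric", "value")
  if (!all(need %in% names(out)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  class(out) <- c("cohort_table", "data.frame")
  out
}
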