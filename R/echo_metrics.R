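# Transthoracic-echo valvular hemodynamics from Doppler velocity envelopes:
# ejection-window gating, velocity-time integral, transvalvular peak velocity
# and pressure gradients (simplified Bernoulli), continuity-equation
# effective orifice area, indexed EOA and discharge coefficient.

#' Construct a Doppler velocity trace
#'
#' @param t Sample times in seconds, strictly increasing, uniformly sampled
#'   (sampling jitter beyond 1% of the nominal interval is rejected).
#' @param v Velocity envelope in m/s, forward flow positive.
#' @param modality `"CW"` (continuous-wave) or `"PW"` (pulsed-wave).
#' @param site Interrogation site, `"aortic-valve"` or `"LVOT"`.
#' @return An object of class `doppler_trace`.
#' @export
doppler_trace <- function(t, v, modality = c("CW", "PW"),
                          site = c("aortic-valve", "LVOT")) {
  modality <- match.arg(modality)
  site <- match.arg(site)
  t <- as.numeric(t); v <- as.numeric(v)
  if (length(t) != length(v) || length(t) < 4L)
    stop("t and v must be equal-length vectors with at least 4 samples")
  if (any(!is.finite(t)) || any(!is.finite(v))) stop("t and v must be finite")
  dtv <- diff(t)
  if (any(dtv <= 0)) stop("t must be strictly increasing")
  if (max(abs(dtv - mean(dtv))) > 0.01 * mean(dtv))
    stop("sampling is not uniform within 1% jitter")
  structure(list(t = t, v = v, modality = modality, site = site),
            class = "doppler_trace")
}

#' Detect the ejection window of a Doppler trace
#'
#' Finds the longest contiguous interval where the envelope exceeds
#' `threshold_frac` of its maximum (default 10%, the standard envelope-gating
#' choice); the window edges are placed at the threshold crossings by linear
#' interpolation between samples.
#'
#' @param trace A [doppler_trace()].
#' @param threshold_frac Fraction of the envelope maximum defining the gate.
#' @return Numeric length-2 vector `(t_start, t_end)` in seconds.
#' @export
detect_ejection_window <- function(trace, threshold_frac = 0.1) {
  stopifnot(inherits(trace, "doppler_trace"))
  v <- trace$v; t <- trace$t
  vmax <- max(v)
  if (vmax <= 0) stop("trace has no forward flow (all-zero or negative envelope)")
  thr <- threshold_frac * vmax
  above <- v > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) stop("no samples above the ejection threshold")
  cross <- function(i_lo, i_hi) {
    # linear interpolation of the time where v crosses thr between two samples
    t[i_lo] + (thr - v[i_lo]) * (t[i_hi] - t[i_lo]) / (v[i_hi] - v[i_lo])
  }
  best <- NULL; best_len <- -Inf
  for (ri in runs) {
    i0 <- starts[ri]; i1 <- ends[ri]
    t0 <- if (i0 > 1L) cross(i0 - 1L, i0) else t[i0]
    t1 <- if (i1 < length(t)) cross(i1 + 1L, i1) else t[i1]
    if (t1 - t0 > best_len) { best <- c(t0, t1); best_len <- t1 - t0 }
  }
  best
}

# Envelope restricted to a window, with linearly interpolated edge samples.
.window_samples <- function(trace, window) {
  t <- trace$t; v <- trace$v
  if (length(window) != 2L || window[2L] <= window[1L]) stop("empty window")
  if (window[1L] < t[1L] - 1e-12 || window[2L] > t[length(t)] + 1e-12)
    stop("window extends beyond the trace")
  inner <- which(t > window[1L] & t < window[2L])
  tt <- c(window[1L], t[inner], window[2L])
  vv <- c(stats::approx(t, v, xout = window[1L])$y, v[inner],
          stats::approx(t, v, xout = window[2L])$y)
  keep <- !duplicated(tt)
  list(t = tt[keep], v = vv[keep])
}

#' Velocity-time integral over a window
#'
#' Trapezoidal integral of the envelope over the window, reported in cm
#' (m/s x s x 100).
#'
#' @param trace A [doppler_trace()].
#' @param window Length-2 vector `(t_start, t_end)` in seconds, e.g. from
#'   [detect_ejection_window()].
#' @return VTI in cm.
#' @export
compute_vti <- function(trace, window) {
  s <- .window_samples(trace, window)
  n <- length(s$t)
  integral <- sum(diff(s$t) * (s$v[-1] + s$v[-n]) / 2)
  integral * 100
}

#' Transvalvular peak velocity and pressure gradients
#'
#' From a continuous-wave aortic-valve trace: TPV is the envelope maximum in
#' the window; the peak transvalvular gradient follows the simplified
#' Bernoulli relation `4 v^2` (mmHg, v in m/s) and the mean gradient is the
#' time average of `4 v(t)^2` over the ejection window.
#'
#' @param trace A [doppler_trace()] with `modality == "CW"` (transvalvular
#'   gradients require continuous-wave interrogation).
#' @param window Ejection window `(t_start, t_end)` in seconds.
#' @return List with `tpv` (m/s), `mean_tpg` (mmHg), `peak_tpg` (mmHg).
#' @export
compute_tpv_tpg <- function(trace, window) {
  stopifnot(inherits(trace, "doppler_trace"))
  if (trace$modality != "CW")
    stop("transvalvular gradients require a continuous-wave (CW) trace")
  s <- .window_samples(trace, window)
  tpv <- max(s$v)
  g <- 4 * s$v^2
  n <- length(s$t)
  mean_tpg <- sum(diff(s$t) * (g[-1] + g[-n]) / 2) / (s$t[n] - s$t[1])
  list(tpv = tpv, mean_tpg = mean_tpg, peak_tpg = 4 * tpv^2)
}

#' Effective orifice area by the continuity equation
#'
#' The left-ventricular outflow tract (LVOT) stroke volume, the LVOT
#' cross-sectional area times the LVOT VTI, must equal the stroke volume
#' through the valve, so
#' \deqn{EOA = \pi (d/2)^2 \cdot VTI_{LVOT} / VTI_{AV}.}
#'
#' @param lvot_diameter_cm LVOT diameter in cm.
#' @param vti_lvot_cm LVOT (pulsed-wave) VTI in cm.
#' @param vti_av_cm Aortic-valve (continuous-wave) VTI in cm.
#' @return EOA in cm^2.
#' @export
compute_eoa <- function(lvot_diameter_cm, vti_lvot_cm, vti_av_cm) {
  for (x in c(lvot_diameter_cm, vti_lvot_cm, vti_av_cm)) {
    if (!is.finite(x) || x <= 0) stop("all continuity-equation inputs must be positive")
  }
  pi * (lvot_diameter_cm / 2)^2 * vti_lvot_cm / vti_av_cm
}

#' Indexed EOA and discharge coefficient
#'
#' EOAi normalizes EOA by body surface area; the discharge coefficient
#' normalizes it by the valve's geometric orifice area (the area when fully
#' open, from the manufacturer's specification sheet), removing label-size
#' differences between subjects.
#'
#' @param eoa_cm2 Effective orifice area (cm^2).
#' @param bsa_m2 Body surface area (m^2).
#' @param goa_cm2 Geometric orifice area (cm^2).
#' @return List with `eoai` (cm^2/m^2) and `discharge_coefficient`.
#' @export
compute_eoai_and_dc <- function(eoa_cm2, bsa_m2, goa_cm2) {
  if (!is.finite(bsa_m2) || bsa_m2 <= 0) stop("bsa must be positive")
  if (!is.finite(goa_cm2) || goa_cm2 <= 0) stop("geometric orifice area must be positive")
  if (!is.finite(eoa_cm2) || eoa_cm2 <= 0) stop("eoa must be positive")
  list(eoai = eoa_cm2 / bsa_m2, discharge_coefficient = eoa_cm2 / goa_cm2)
}

#' Full echo assessment from two Doppler traces
#'
#' Computes the complete set of valvular metrics: TPV, mean/peak TPG, the two
#' VTIs, EOA, EOAi and discharge coefficient.
#'
#' @param av_trace Continuous-wave aortic-valve [doppler_trace()].
#' @param lvot_trace Pulsed-wave LVOT [doppler_trace()].
#' @param lvot_diameter_cm LVOT diameter (cm).
#' @param bsa_m2 Body surface area (m^2).
#' @param goa_cm2 Geometric orifice area (cm^2).
#' @return A list of class `echo_metrics` with fields `tpv`, `mean_tpg`,
#'   `peak_tpg`, `vti_av`, `vti_lvot`, `eoa`, `eoai`,
#'   `discharge_coefficient`.
#' @export
assess_echo <- function(av_trace, lvot_trace, lvot_diameter_cm, bsa_m2,
                        goa_cm2) {
  win_av <- detect_ejection_window(av_trace)
  win_lvot <- detect_ejection_window(lvot_trace)
  vti_av <- compute_vti(av_trace, win_av)
  vti_lvot <- compute_vti(lvot_trace, win_lvot)
  tpg <- compute_tpv_tpg(av_trace, win_av)
  eoa <- compute_eoa(lvot_diameter_cm, vti_lvot, vti_av)
  idx <- compute_eoai_and_dc(eoa, bsa_m2, goa_cm2)
  structure(c(tpg, list(vti_av = vti_av, vti_lvot = vti_lvot, eoa = eoa),
              idx),
            class = "echo_metrics")
}

#' @export
print.echo_metrics <- function(x, ...) {
  cat(sprintf(paste0("<echo_metrics>\n",
                     "  TPV       %.3g m/s   peak TPG %.3g mmHg   mean TPG %.3g mmHg\n",
                     "  VTI (AV)  %.3g cm    VTI (LVOT) %.3g cm\n",
                     "  EOA       %.3g cm^2  EOAi %.3g cm^2/m^2  discharge coeff %.3g\n"),
              x$tpv, x$peak_tpg, x$mean_tpg, x$vti_av, x$vti_lvot,
              x$eoa, x$eoai, x$discharge_coefficient))
  invisible(x)
}
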