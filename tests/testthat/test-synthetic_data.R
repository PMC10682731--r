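test_that("phantom ground truths match independent closed forms / quadrature", {
  # Poiseuille: total = 2 pi mu L U^2; density = 2 mu U^2 / R^2;
  # mean |omega| = (4/3) U / R  (all SI)
  ph <- make_phantom("poiseuille", params = list(R = 10, L = 100, U = 1),
                     shape = c(10, 10, 42), spacing = c(2.5, 2.5, 2.5),
                     nt = 1, waveform = 1)
  mu <- 3.2e-3
  expect_equal(ph$truth$analytic_total_velr_W, 2 * pi * mu * 0.1 * 1,
               tolerance = 1e-12)
  expect_equal(ph$truth$analytic_velr_density_W_m3, 2 * mu * 1 / 0.01^2,
               tolerance = 1e-12)
  expect_equal(ph$truth$analytic_mean_vorticity_s1, (4 / 3) / 0.01,
               tolerance = 1e-12)

  rot <- make_phantom("solid_rotation", params = list(omega0 = 10),
                      shape = c(36, 36, 42), nt = 1, waveform = 1)
  expect_identical(rot$truth$analytic_total_velr_W, 0)
  expect_equal(rot$truth$analytic_mean_vorticity_s1, 20)

  # Lamb-Oseen: check the stored quadrature against an independent one on
  # the dissipation of v_theta(r) evaluated by numerical differentiation
  lo <- make_phantom("lamb_oseen", params = list(R = 40, L = 100,
                                                 gamma = 0.01, r_c = 10),
                     shape = c(36, 36, 42), nt = 1, waveform = 1)
  vth <- function(r) 0.01 / (2 * pi * r) * (1 - exp(-(r / 0.01)^2))
  eps <- 1e-7
  phi <- function(r) {
    dv <- (vth(r + eps) - vth(r - eps)) / (2 * eps)
    3.2e-3 * (dv - vth(r) / r)^2
  }
  ref <- 0.1 * stats::integrate(function(r) phi(r) * 2 * pi * r, 1e-6, 0.04,
                                rel.tol = 1e-9)$value
  expect_equal(lo$truth$analytic_total_velr_W, ref, tolerance = 1e-4)
  expect_equal(lo$truth$analytic_mean_vorticity_s1,
               0.01 * (1 - exp(-16)) / (pi * 0.04^2), tolerance = 1e-12)

  # uniform: everything zero
  un <- make_phantom("uniform", params = list(u = c(0.9, 0, 0)),
                     shape = c(6, 6, 6), nt = 1, waveform = 1)
  expect_identical(un$truth$analytic_total_velr_W, 0)
  expect_identical(un$truth$analytic_mean_vorticity_s1, 0)
})

test_that("phantom contract: waveform scaling, noise, wrap band, geometry errors", {
  wf <- c(0.3, 1, 0.6, 0.1)
  ph <- make_phantom("shear", params = list(k = 5), shape = c(6, 6, 6),
                     spacing = c(3, 3, 3), nt = 4, waveform = wf)
  expect_equal(ph$field$vx[, , , 3], ph$field$vx[, , , 2] * 0.6,
               tolerance = 1e-12)
  expect_identical(ph$truth$peak_frame, 2L)

  # noise is reproducible and has the requested scale
  n1 <- make_phantom("uniform", shape = c(12, 12, 12), nt = 2,
                     noise_sd = 0.05, rng_seed = 3)
  n2 <- make_phantom("uniform", shape = c(12, 12, 12), nt = 2,
                     noise_sd = 0.05, rng_seed = 3)
  expect_identical(n1$field$vy, n2$field$vy)
  expect_equal(sd(n1$field$vy), 0.05, tolerance = 0.05)

  # wrapped values lie in (-venc, venc]
  w <- make_phantom("poiseuille", params = list(R = 10, L = 40, U = 2.4),
                    shape = c(10, 10, 18), nt = 4, waveform = c(0.5, 1, 0.8, 0.2),
                    venc = 150, apply_wrap = TRUE)
  expect_true(all(w$field$vz > -1.5 - 1e-12 & w$field$vz <= 1.5 + 1e-12))
  expect_true(any(w$field$vz != w$truth$prewrap$vz))

  expect_error(make_phantom("poiseuille", params = list(R = 40, L = 40),
                            shape = c(10, 10, 18)), "exceeds the grid")
  expect_error(make_phantom("uniform", shape = c(6, 6, 6), noise_sd = -1),
               "noise_sd")
})

test_that("pipeline summaries converge to the phantom ground truth", {
  # second-order convergence is exercised in the acceptance suite; here a
  # single mid-resolution check that generator truth and pipeline agree
  ph <- make_phantom("poiseuille", params = list(R = 10, L = 100, U = 1),
                     shape = c(18, 18, 82), spacing = rep(1.25, 3),
                     nt = 1, waveform = 1)
  q <- quantify_hemodynamics(ph$field, ph$mask)
  expect_equal(q$summary$total_velr_mW / 1000, ph$truth$analytic_total_velr_W,
               tolerance = 0.05)
  expect_equal(q$summary$mean_vorticity_s1, ph$truth$analytic_mean_vorticity_s1,
               tolerance = 0.05)
})

test_that("Doppler generator: closed-form truth and degenerate cases", {
  s <- synthesize_doppler(tpv = 1.9, pulse_width = 0.3, cycle = 1)
  expect_equal(s$truth$vti_cm, 2 * 1.9 * 0.3 / pi * 100, tolerance = 1e-12)
  expect_equal(s$truth$peak_tpg_mmHg, 14.44, tolerance = 1e-12)
  expect_equal(s$truth$mean_tpg_mmHg, 7.22, tolerance = 1e-12)
  z <- synthesize_doppler(tpv = 0)
  expect_identical(z$truth$vti_cm, 0)
  expect_equal(synthesize_doppler(tpv = 1.2)$truth$peak_tpg_mmHg, 5.76)
  expect_error(synthesize_doppler(tpv = 1, pulse_width = 1, cycle = 0.8),
               "pulse_width")
})

test_that("cohort simulator: sizes, determinism, truncation, SD-0, convergence", {
  tab <- simulate_cohort(rng_seed = 1)
  expect_s3_class(tab, "cohort_table")
  expect_equal(length(unique(tab$subject_id)), 52)        # 10 + 6 + 36
  cnt <- table(unique(tab[, c("subject_id", "group")])$group)
  expect_equal(as.integer(cnt[c("On-X", "SJM/CM", "healthy")]), c(10, 6, 36))
  # every subject has every metric exactly once
  expect_true(all(table(tab$subject_id, tab$metric) == 1))
  expect_true(all(tab$value >= 0))

  expect_identical(simulate_cohort(rng_seed = 7), simulate_cohort(rng_seed = 7))
  expect_false(identical(simulate_cohort(rng_seed = 7),
                         simulate_cohort(rng_seed = 8)))

  sp <- list(list(name = "g", n = 5L,
                  metrics = data.frame(metric = "m", mean = 3, sd = 0)))
  expect_true(all(simulate_cohort(sp, rng_seed = 1)$value == 3))
  expect_error(simulate_cohort(list(list(name = "g", n = 1L,
    metrics = data.frame(metric = "m", mean = 1, sd = 1)))), "n >= 2")

  # sample means approach spec means at ~SD/sqrt(n)
  spc <- list(list(name = "g", n = 400L,
                   metrics = data.frame(metric = "m", mean = 50, sd = 10)))
  devs <- sapply(1:20, function(s) mean(simulate_cohort(spc, rng_seed = s)$value) - 50)
  expect_lt(abs(mean(devs)), 0.5)
  expect_equal(sd(devs), 10 / sqrt(400), tolerance = 0.5)

  # round trip through CSV
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, tmp)
  back <- read_cohort(tmp)
  expect_equal(back$value, tab$value, tolerance = 1e-12)
})
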