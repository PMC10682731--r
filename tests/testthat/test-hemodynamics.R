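test_that("peak systole is the argmax of in-mask mean speed, earliest on ties", {
  wf7 <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 1.0, 0.2)   # peaks at frame 7
  ph <- make_phantom("poiseuille", params = list(R = 10, L = 40, U = 1),
                     shape = c(10, 10, 18), spacing = c(2.5, 2.5, 2.5),
                     nt = 8, waveform = wf7)
  expect_identical(detect_peak_systole(ph$field, ph$mask), ph$truth$peak_frame)
  expect_identical(detect_peak_systole(ph$field, ph$mask), 7L)

  # single frame -> frame 1; exact tie -> earlier frame
  ph1 <- make_phantom("uniform", params = list(u = c(0.3, 0, 0)),
                      shape = c(4, 4, 4), nt = 1, waveform = 1)
  expect_identical(detect_peak_systole(ph1$field, ph1$mask), 1L)
  tie <- make_phantom("uniform", params = list(u = c(0.3, 0, 0)),
                      shape = c(4, 4, 4), nt = 4, waveform = c(0.2, 1, 1, 0.5))
  expect_identical(detect_peak_systole(tie$field, tie$mask), 2L)
  expect_error(detect_peak_systole(ph$field, make_phantom("uniform",
    shape = c(9, 9, 9), nt = 1, waveform = 1)$mask), "does not match")
})

test_that("gradient tensor is exact on linear fields, including one-sided edges", {
  # linear shear vx = k y, k = 5 1/s: dvx/dy = 5 everywhere (one-sided
  # differences are exact on linear fields too)
  f <- tiny_field(function(x, y, z) 5 * y,
                  function(x, y, z) 0 * x,
                  function(x, y, z) 0 * x)
  G <- velocity_gradient(f, 1, full_mask())
  expect_equal(max(abs(G[, , , 1, 2] - 5)), 0, tolerance = 1e-12)
  others <- c(G[, , , 1, 1], G[, , , 1, 3], G[, , , 2, ], G[, , , 3, ])
  expect_equal(max(abs(others)), 0, tolerance = 1e-12)

  # uniform translation: zero tensor everywhere
  fu <- tiny_field(function(x, y, z) 1 + 0 * x,
                   function(x, y, z) 0 * x, function(x, y, z) 0 * x)
  Gu <- velocity_gradient(fu, 1, full_mask())
  expect_equal(max(abs(Gu)), 0, tolerance = 1e-12)

  # central_only policy leaves boundary voxels undefined
  Gc <- velocity_gradient(f, 1, full_mask(), boundary_policy = "central_only")
  expect_true(all(is.na(Gc[1, , , 1, 1])))
  expect_false(anyNA(Gc[2:7, 2:7, 2:7, , ]))
})

test_that("Poiseuille interior gradient matches the analytic profile to 2nd order", {
  errs <- sapply(c(2.5, 1.25), function(h) {
    n <- 2 * ceiling(11 / h)
    ph <- make_phantom("poiseuille", params = list(R = 10, L = 40, U = 1),
                       shape = c(n, n, ceiling(44 / h)), spacing = rep(h, 3),
                       nt = 1, waveform = 1)
    G <- velocity_gradient(ph$field, 1, ph$mask)
    co <- grid_coords(dim(ph$mask$voxels), rep(h, 3))
    # analytic dvz/dx = -2 U x / R^2 (x in m, R in m)
    an <- -2 * (co$X / 1000) / 0.01^2
    sel <- erode_mask(ph$mask)$voxels
    max(abs(G[, , , 3, 1][sel] - an[sel]))
  })
  expect_lt(errs[2], 1e-9)     # quadratic profile: central differences exact
  expect_lt(errs[1], 1e-9)
})

test_that("VELR closed forms: rigid motion zero, shear mu k^2", {
  cfg <- analysis_config(mu = 3.2e-3)
  # rigid motion = translation + solid rotation: zero dissipation
  f <- tiny_field(function(x, y, z) 0.4 - 10 * y,
                  function(x, y, z) -0.1 + 10 * x,
                  function(x, y, z) 0.2 + 0 * x)
  velr <- compute_velr_map(velocity_gradient(f, 1, full_mask()), cfg)
  expect_lt(max(velr$values), 1e-24)

  fs <- tiny_field(function(x, y, z) 5 * y, function(x, y, z) 0 * x,
                   function(x, y, z) 0 * x)
  gs <- velocity_gradient(fs, 1, full_mask())
  velrs <- compute_velr_map(gs, cfg)
  expect_equal(unique(round(as.vector(velrs$values), 12)), 3.2e-3 * 25)
  # divergence-free field: correction term changes nothing
  velrs2 <- compute_velr_map(gs, analysis_config(mu = 3.2e-3,
                                                 include_divergence_term = TRUE))
  expect_equal(velrs2$values, velrs$values)
})

test_that("vorticity: uniform zero, solid rotation 2 omega0, Lamb-Oseen Gaussian", {
  fu <- tiny_field(function(x, y, z) 0.7 + 0 * x, function(x, y, z) 0 * x,
                   function(x, y, z) 0 * x)
  wu <- compute_vorticity_map(velocity_gradient(fu, 1, full_mask()))
  expect_equal(max(abs(wu$values)), 0, tolerance = 1e-12)

  ph <- make_phantom("solid_rotation", params = list(R = 30, L = 60, omega0 = 10),
                     shape = c(28, 28, 14), spacing = c(2.5, 2.5, 5),
                     nt = 1, waveform = 1)
  g <- velocity_gradient(ph$field, 1, ph$mask)
  w <- vector_map_magnitude(compute_vorticity_map(g))
  interior <- erode_mask(ph$mask)$voxels
  expect_equal(max(abs(w$values[interior] - 20)), 0, tolerance = 1e-10)
  velr <- compute_velr_map(g, analysis_config())
  expect_lt(max(velr$values[interior]), 1e-24)

  # Lamb-Oseen: omega_z(r) = Gamma/(pi r_c^2) exp(-r^2/r_c^2), 2nd order
  errs <- sapply(c(4, 2), function(h) {
    n <- 2 * ceiling(42 / h)
    ph2 <- make_phantom("lamb_oseen",
                        params = list(R = 40, L = 3 * h, gamma = 0.01, r_c = 10),
                        shape = c(n, n, 4), spacing = c(h, h, h), nt = 1,
                        waveform = 1)
    g2 <- velocity_gradient(ph2$field, 1, ph2$mask)
    wz <- compute_vorticity_map(g2)$values[, , , 3]
    co <- grid_coords(dim(ph2$mask$voxels), rep(h, 3))
    r_m <- sqrt(co$X^2 + co$Y^2) / 1000
    an <- 0.01 / (pi * 0.01^2) * exp(-(r_m / 0.01)^2)
    sel <- erode_mask(ph2$mask)$voxels
    max(abs(wz[sel] - an[sel])) / max(an)
  })
  expect_lt(errs[2], 0.02)
  expect_gt(errs[1] / errs[2], 2.5)   # ~4x expected at 2nd order
})

test_that("maps match the naive triple-loop reference voxel-for-voxel on 8^3", {
  set.seed(42)
  sh <- c(8, 8, 8)
  mk <- function() array(rnorm(prod(sh), sd = 0.3), c(sh, 1))
  f <- velocity_field(mk(), mk(), mk(), spacing = c(3.4, 2.4, 2.9), dt = 40,
                      venc = 250, origin = c(0, 0, 0))
  mask_arr <- array(runif(prod(sh)) > 0.3, sh)
  mask_arr[1] <- TRUE
  mask <- segmentation_mask(mask_arr)
  G <- velocity_gradient(f, 1, mask)
  Gref <- brute_gradient(f, 1, mask$voxels, c(3.4, 2.4, 2.9))
  expect_identical(dim(G)[1:5], dim(Gref)[1:5])
  expect_equal(unclass(G)[seq_along(Gref)], as.vector(Gref))

  velr <- compute_velr_map(G, analysis_config(mu = 3.2e-3))
  expect_equal(as.vector(velr$values), as.vector(brute_velr(Gref, 3.2e-3)))
  w <- compute_vorticity_map(G)
  wref <- brute_vorticity(Gref)
  expect_equal(as.vector(w$values), as.vector(wref))
})

test_that("Galilean invariance and rotation additivity hold at interior voxels", {
  set.seed(7)
  ph <- make_phantom("lamb_oseen", params = list(R = 30, L = 40, gamma = 0.008,
                                                 r_c = 12),
                     shape = c(26, 26, 18), spacing = c(2.5, 2.5, 2.5), nt = 1,
                     waveform = 1, noise_sd = 0.02, rng_seed = 9)
  interior <- erode_mask(ph$mask)$voxels
  g0 <- velocity_gradient(ph$field, 1, ph$mask)
  velr0 <- compute_velr_map(g0)$values
  vort0 <- compute_vorticity_map(g0)$values

  # add a constant vector: nothing changes anywhere (not only interior)
  ft <- ph$field
  ft$vx <- ft$vx + 0.37; ft$vy <- ft$vy - 0.12; ft$vz <- ft$vz + 0.9
  gt <- velocity_gradient(ft, 1, ph$mask)
  expect_equal(compute_velr_map(gt)$values, velr0, tolerance = 1e-9)
  expect_equal(compute_vorticity_map(gt)$values, vort0, tolerance = 1e-9)

  # superpose solid-body rotation omega0 about z: vorticity gains exactly
  # (0, 0, 2 omega0); VELR unchanged (linear field: exact even one-sided)
  omega0 <- 4
  co <- grid_coords(dim(ph$mask$voxels), c(2.5, 2.5, 2.5))
  fr <- ph$field
  fr$vx <- fr$vx + array(-omega0 * co$Y / 1000, dim(fr$vx))
  fr$vy <- fr$vy + array(omega0 * co$X / 1000, dim(fr$vy))
  gr <- velocity_gradient(fr, 1, ph$mask)
  velr_r <- compute_velr_map(gr)$values
  vort_r <- compute_vorticity_map(gr)$values
  expect_equal(velr_r[interior], velr0[interior], tolerance = 1e-8)
  dz <- vort_r[, , , 3] - vort0[, , , 3]
  expect_equal(range(dz[interior]), rep(2 * omega0, 2), tolerance = 1e-8)
  expect_equal(vort_r[, , , 1][interior], vort0[, , , 1][interior],
               tolerance = 1e-8)
})

test_that("ROI summary units and consistency: total = density x volume", {
  ph <- make_phantom("shear", params = list(k = 5), shape = c(10, 10, 10),
                     spacing = c(2, 2, 2), nt = 1, waveform = 1)
  q <- quantify_hemodynamics(ph$field, ph$mask)
  s <- q$summary
  # constant VELR c = mu k^2 over the ROI: density = c, total = c * V
  expect_equal(s$velr_density_W_m3, 3.2e-3 * 25, tolerance = 1e-12)
  expect_equal(s$roi_volume_m3, prod(c(20, 20, 20) / 1000), tolerance = 1e-12)
  expect_equal(s$total_velr_mW / 1000, s$velr_density_W_m3 * s$roi_volume_m3,
               tolerance = 1e-12)
  expect_equal(s$mean_vorticity_s1, 5, tolerance = 1e-12)
  expect_error(summarize_roi(q$velr_map, q$vorticity_map,
                             full_mask(c(9, 9, 9))), "same grid")
})
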