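test_that("interferogram formation obeys the cross-term identity", {
  k <- seq(4.5, 5.3, length.out = 32)
  set.seed(8)
  a_s <- complex(real = rnorm(32), imaginary = rnorm(32))
  a_m <- complex(real = rnorm(32), imaginary = rnorm(32))
  ig <- make_interferogram(a_s, a_m, k)
  expect_true(all(ig$I >= 0))
  expect_equal(ig$I - Mod(a_s)^2 - Mod(a_m)^2,
               2 * Re(a_s * Conj(a_m)))
  expect_equal(make_interferogram(0 * a_s, a_m, k)$I, Mod(a_m)^2)
  expect_equal(make_interferogram(a_s, 0 * a_m, k)$I, Mod(a_s)^2)
  expect_error(make_interferogram(a_s[1:10], a_m, k), "equal length")
})

test_that("A-scan reconstruction places a single reflector at its depth", {
  sys <- small_sys(Nk = 128, zf = 300)
  am <- mirror_modal_coefficient(sys)
  one <- scatterer_set(0, 0, 300, 1)
  ig <- simulate_spectrum(one, sys, backend = "rigorous", alpha_mirr = am)
  a <- make_ascan(ig, "complex")
  peak <- a$z_axis[which.max(Mod(a$A))]
  expect_lt(abs(peak - 300), a$dz)     # within one depth pixel
  # real-spectrum mode is Hermitian on the wrapped axis
  a2 <- make_ascan(ig, "subtract")
  n <- length(a2$A)
  expect_equal(a2$A[2:n], Conj(a2$A[n:2]), tolerance = 1e-10)
  # non-uniform wavenumber grids are rejected
  bad <- ig; bad$k_grid[5] <- bad$k_grid[5] * 1.001
  expect_error(make_ascan(bad), "uniform")
})

test_that("a rigid axial shift moves the A-scan by the same amount", {
  sys <- acc_sys()
  m <- acc_msr(); da <- acc_da(); am <- acc_mirror()
  scat <- generate_disc_phantom(70, c(100, 800), n = 150, seed = 3)
  shifted <- scatterer_set(scat$x, scat$y, scat$z + 10, scat$rho_s)
  a0 <- make_ascan(simulate_spectrum(scat, sys, backend = "taylor_msr",
                                     da = da, msr = m, alpha_mirr = am),
                   "complex")
  a1 <- make_ascan(simulate_spectrum(shifted, sys, backend = "taylor_msr",
                                     da = da, msr = m, alpha_mirr = am),
                   "complex")
  cc <- stats::ccf(Mod(a1$A), Mod(a0$A), lag.max = 8, plot = FALSE)
  lag <- cc$lag[which.max(cc$acf)]
  expect_lt(abs(lag * a0$dz - 10), a0$dz)
})

test_that("a 1x1 scan degenerates to the direct A-scan path", {
  sys <- small_sys(Nk = 64, zf = 200)
  m <- msr_fit(sys, L = 21, D = 15, rho_max = 70, z_max = 400)
  g <- source_grid(70, 400, 28, 190)
  da <- derivative_array(g, sys, k = m$kj, k_index = m$anchor_idx)
  am <- mirror_modal_coefficient(sys)
  scat <- generate_disc_phantom(60, c(50, 380), n = 80, seed = 10)
  cs <- simulate_cscan(scat, scan_geometry(3, -2, 70), sys,
                       backend = "taylor_msr", da = da, msr = m,
                       alpha_mirr = am)
  direct <- make_ascan(simulate_spectrum(scat, sys, x0 = 3, y0 = -2,
                                         rho_max = 70,
                                         backend = "taylor_msr", da = da,
                                         msr = m, alpha_mirr = am),
                       "complex", eta = sys$eta)
  expect_identical(as.vector(cs$A[1, 1, ]), direct$A)
  expect_equal(cs$z_axis, direct$z_axis)
})

test_that("scaling every cross-section scales spectra and A-scans linearly", {
  sys <- small_sys(Nk = 64, zf = 200)
  m <- msr_fit(sys, L = 21, D = 15, rho_max = 70, z_max = 400)
  g <- source_grid(70, 400, 28, 190)
  da <- derivative_array(g, sys, k = m$kj, k_index = m$anchor_idx)
  am <- mirror_modal_coefficient(sys)
  scat <- generate_disc_phantom(60, c(50, 380), n = 60, seed = 14)
  scaled <- scatterer_set(scat$x, scat$y, scat$z, scat$rho_s * 2.5)
  ig1 <- simulate_spectrum(scat, sys, backend = "taylor_msr", da = da,
                           msr = m, alpha_mirr = am)
  ig2 <- simulate_spectrum(scaled, sys, backend = "taylor_msr", da = da,
                           msr = m, alpha_mirr = am)
  expect_equal(ig2$alpha_scat, 2.5 * ig1$alpha_scat, tolerance = 1e-12)
  a1 <- make_ascan(ig1, "complex"); a2 <- make_ascan(ig2, "complex")
  expect_equal(a2$A, 2.5 * a1$A, tolerance = 1e-12)
})

test_that("translating the sample by one scan step shifts the scan by one pixel", {
  sys <- small_sys(Nk = 48, zf = 150)
  m <- msr_fit(sys, L = 17, D = 15, rho_max = 70, z_max = 300)
  g <- source_grid(70, 300, 28, 190)
  da <- derivative_array(g, sys, k = m$kj, k_index = m$anchor_idx)
  am <- mirror_modal_coefficient(sys)
  # coordinates snapped to exact quarters so the beam-frame arithmetic is
  # bit-identical after translation
  base <- generate_uniform_phantom(c(-40, 40), c(-20, 20), c(50, 280),
                                   n = 120, seed = 2)
  snap <- function(v) round(v * 4) / 4
  scat <- scatterer_set(snap(base$x), snap(base$y), snap(base$z), 1)
  moved <- scatterer_set(scat$x + 4, scat$y, scat$z, 1)
  scan <- scan_geometry(seq(-8, 8, by = 4), 0, rho_max = 70)
  cs0 <- simulate_cscan(scat, scan, sys, backend = "taylor_msr", da = da,
                        msr = m, alpha_mirr = am)
  cs1 <- simulate_cscan(moved, scan, sys, backend = "taylor_msr", da = da,
                        msr = m, alpha_mirr = am)
  for (ix in 2:5) {
    expect_identical(cs1$A[ix, 1, ], cs0$A[ix - 1, 1, ])
  }
})

test_that("fast backends refuse to run without their artifacts", {
  sys <- small_sys(Nk = 16)
  scat <- scatterer_set(0, 0, 100, 1)
  am <- complex(real = numeric(16))
  expect_error(simulate_spectrum(scat, sys, backend = "taylor",
                                 alpha_mirr = am), "fit-grid")
  g <- source_grid(70, 300, 28, 190)
  da <- derivative_array(g, sys, k = wavenumber_grid(sys)[c(1, 16)])
  expect_error(simulate_spectrum(scat, sys, backend = "taylor", da = da,
                                 alpha_mirr = am), "full")
  expect_error(simulate_spectrum(scat, sys, backend = "taylor_msr", da = da,
                                 alpha_mirr = am), "fit-msr")
})

test_that("heterogeneous cross-sections produce the expected region contrast", {
  sys <- small_sys(Nk = 96, zf = 175)
  m <- msr_fit(sys, L = 25, D = 15, rho_max = 70, z_max = 320)
  g <- source_grid(70, 320, 28, 190)
  da <- derivative_array(g, sys, k = m$kj, k_index = m$anchor_idx)
  am <- mirror_modal_coefficient(sys)
  scat <- generate_uniform_phantom(c(-60, 60), c(-20, 20), c(50, 300),
                                   density = 0.00390625, seed = 17,
                                   regions = list(list(
                                     x_range = c(5, 60),
                                     y_range = c(-20, 20),
                                     z_range = c(50, 300), multiplier = 5)))
  scan <- scan_geometry(seq(-35, 35, by = 10), 0, rho_max = 70)
  cs <- simulate_cscan(scat, scan, sys, backend = "taylor_msr", da = da,
                       msr = m, alpha_mirr = am)
  bins <- which(cs$z_axis >= 100 & cs$z_axis <= 250)
  p <- apply(Mod(cs$A[, 1, bins])^2, 1, mean)
  bright <- p[cs$x_positions > 10]
  dark <- p[cs$x_positions < -10]
  expect_gt(min(bright), max(dark))
})

test_that("loaded series honour their displacement contract", {
  sys <- small_sys(Nk = 64, zf = 200)
  m <- msr_fit(sys, L = 21, D = 15, rho_max = 70, z_max = 400)
  g <- source_grid(70, 400, 28, 190, D_z0 = 1)
  da <- derivative_array(g, sys, k = m$kj, k_index = m$anchor_idx)
  am <- mirror_modal_coefficient(sys)
  scat <- generate_disc_phantom(60, c(50, 380), n = 80, seed = 19)
  scan <- scan_geometry(0, 0, 70)
  # identity displacement: every step identical to the unloaded scan
  series <- simulate_loaded_series(scat, matrix(0, scat$Ns, 2), scan, sys,
                                   backend = "taylor_msr", da = da, msr = m,
                                   alpha_mirr = am, Ms = 1)
  expect_identical(series[[2]]$A, series[[1]]$A)
  expect_identical(series[[3]]$A, series[[1]]$A)
  # violations of the declared maximum are refused
  expect_error(simulate_loaded_series(scat, matrix(2, scat$Ns, 1), scan, sys,
                                      backend = "taylor_msr", da = da,
                                      msr = m, alpha_mirr = am, Ms = 1),
               "exceeds")
  # a derivative array without enough displacement orders is refused
  expect_error(simulate_loaded_series(scat, matrix(9, scat$Ns, 1), scan, sys,
                                      backend = "taylor_msr", da = da,
                                      msr = m, alpha_mirr = am, Ms = 9),
               "D_z0")
})

test_that("a loaded step equals re-simulating the displaced sample from scratch", {
  sys <- small_sys(Nk = 64, zf = 200)
  m <- msr_fit(sys, L = 21, D = 15, rho_max = 70, z_max = 400)
  scat <- generate_disc_phantom(60, c(50, 380), n = 100, seed = 23)
  loaded <- apply_uniform_strain(scat, -0.003)
  g <- source_grid(70, 400, 28, 190, D_z0 = choose_Dz0(loaded$Ms))
  da <- derivative_array(g, sys, k = m$kj, k_index = m$anchor_idx)
  am <- mirror_modal_coefficient(sys)
  scan <- scan_geometry(0, 0, 70)
  series <- simulate_loaded_series(scat, cbind(loaded$displacement), scan,
                                   sys, backend = "taylor_msr", da = da,
                                   msr = m, alpha_mirr = am)
  fresh <- simulate_cscan(loaded, scan, sys, backend = "taylor_msr",
                          da = da, msr = m, alpha_mirr = am)
  expect_lt(integral_error(fresh$A, series[[2]]$A), 3e-4)
})
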