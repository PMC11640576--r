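test_that("source grids cover the domain with cell-centered sources", {
  g <- source_grid(70, 1000, 28, 190)
  expect_equal(g$N_rho, 3L)
  expect_equal(g$N_z, 6L)
  expect_equal(g$rho_sources, c(14, 42, 70))
  g1 <- source_grid(28, 100, 28, 100)
  expect_equal(g1$N_rho, 1L)
  expect_equal(g1$rho_sources, 14)
  # every point of the domain is within half a spacing of a source
  expect_lte(max(abs(outer(seq(0, 70, by = 0.5), g$rho_sources, "-")
                     |> apply(1, function(d) min(abs(d))))), 14)
  b <- taylor_budget(g, 865)
  expect_equal(b$n_tot, 21 * 9 * 3 * 6 * 865)
})

test_that("nearest-source assignment breaks boundary ties toward the lower index", {
  idx <- octsim:::.cell_index(c(0, 13.9, 28, 28.001, 70), 28, 3L, "radial")
  expect_equal(idx, c(1L, 1L, 1L, 2L, 3L))
  expect_error(octsim:::.cell_index(85, 28, 3L, "radial"), "outside")
  expect_error(octsim:::.cell_index(-1, 28, 3L, "radial"), "outside")
})

test_that("Bessel derivative rows follow the binomial identity", {
  x <- seq(0.1, 30, length.out = 50)
  jtab <- t(vapply(0:6, function(o) besselJ(x, o), numeric(50)))
  # m = 2, c = 2: kernel 2^-2 [J0 - 2 J2 + J4]
  expect_equal(octsim:::.bessel_deriv_row(jtab, 2L, 2L),
               (besselJ(x, 0) - 2 * besselJ(x, 2) + besselJ(x, 4)) / 4)
  # m = 1, c = 0 must equal -J1 (the classic first derivative)
  expect_equal(octsim:::.bessel_deriv_row(jtab, 0L, 1L), -besselJ(x, 1))
})

test_that("stored derivatives match direct quadrature and finite differences", {
  sys <- small_sys()
  k <- wavenumber_grid(sys)[9]
  g <- source_grid(70, 1000, 28, 190, D_rho = 4, D_z = 3)
  da <- derivative_array(g, sys, k = k)
  h <- dwi_h_direct(g$rho_sources[2], g$z_sources[3], k, sys)
  expect_equal(da$S[1, 1, 1, 2, 3, 1], h$h0, tolerance = 1e-12)
  expect_equal(da$S[2, 1, 1, 2, 3, 1], h$h2, tolerance = 1e-12)
  d <- 1e-3
  hp <- dwi_h_direct(g$rho_sources[2] + d, g$z_sources[3], k, sys)
  hm <- dwi_h_direct(g$rho_sources[2] - d, g$z_sources[3], k, sys)
  expect_lt(Mod(da$S[1, 2, 1, 2, 3, 1] - (hp$h0 - hm$h0) / (2 * d)) /
              Mod(da$S[1, 2, 1, 2, 3, 1]), 1e-6)
  hp <- dwi_h_direct(g$rho_sources[2], g$z_sources[3] + d, k, sys)
  hm <- dwi_h_direct(g$rho_sources[2], g$z_sources[3] - d, k, sys)
  expect_lt(Mod(da$S[2, 1, 2, 2, 3, 1] - (hp$h2 - hm$h2) / (2 * d)) /
              Mod(da$S[2, 1, 2, 2, 3, 1]), 1e-6)
})

test_that("Taylor surrogate is exact at source points and converges on fine grids", {
  sys <- small_sys()
  k <- wavenumber_grid(sys)[16]
  g <- source_grid(70, 1000, 28, 190, D_rho = 6, D_z = 4)
  da <- derivative_array(g, sys, k = k)
  th <- taylor_h(g$rho_sources[2], g$z_sources[4], da, 1)
  expect_identical(th$h0, da$S[1, 1, 1, 2, 4, 1])
  expect_identical(th$h2, da$S[2, 1, 1, 2, 4, 1])
  expect_error(taylor_h(100, 500, da, 1), "outside")
  # low order on a fine grid reproduces direct quadrature
  gf <- source_grid(70, 1000, 1, 10, D_rho = 4, D_z = 4)
  daf <- derivative_array(gf, sys, k = k)
  set.seed(4)
  rho <- runif(40, 0, 70); z <- runif(40, 0, 1000)
  th <- taylor_h(rho, z, daf, 1)
  hd <- dwi_h_direct(rho, z, k, sys)
  expect_lt(max(Mod(th$h0 - hd$h0), Mod(th$h2 - hd$h2)) /
              max(Mod(hd$h0)), 1e-6)
})

test_that("error decreases monotonically with expansion order", {
  sys <- small_sys()
  k <- max(wavenumber_grid(sys))
  set.seed(2)
  rho <- runif(120, 0, 70); z <- runif(120, 0, 1000)
  hd <- dwi_h_direct(rho, z, k, sys)
  errs <- vapply(c(4, 8, 12, 16, 20), function(D) {
    g <- source_grid(70, 1000, 28, 190, D_rho = D, D_z = 8)
    th <- taylor_h(rho, z, derivative_array(g, sys, k = k), 1)
    (sum(Mod(th$h0 - hd$h0)^2) + sum(Mod(th$h2 - hd$h2)^2)) /
      (sum(Mod(hd$h0)^2) + sum(Mod(hd$h2)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[5], 3e-4)   # recommended radial order meets the target
})

test_that("fast x-field composes the azimuthal dependence outside the expansion", {
  sys <- small_sys()
  ik <- 9
  k <- wavenumber_grid(sys)[ik]
  g <- source_grid(70, 1000, 28, 190)
  da <- derivative_array(g, sys, k = k)
  # on-axis: psi-independent (up to the tiny h2 truncation residual, since
  # the surrogate's h2 vanishes only approximately at rho = 0)
  e1 <- field_x_fast(0, 0.2, 500, da, 1)
  e2 <- field_x_fast(0, 2.1, 500, da, 1)
  expect_lt(Mod(e1 - e2) / Mod(e1), 1e-4)
  # against the rigorous oracle at scattered points
  set.seed(7)
  rho <- runif(60, 0, 70); psi <- runif(60, 0, 2 * pi); z <- runif(60, 0, 1000)
  ef <- field_x_fast(rho, psi, z, da, 1)
  er <- focal_field_rigorous(rho, psi, z, k, sys)$Ex
  expect_lt(sum(Mod(ef - er)^2) / sum(Mod(er)^2), 3e-4)
  # factored carrier: a half-wavelength axial step flips the phase, up to
  # the slow residual of h
  lam <- 2 * pi / k
  p1 <- field_x_fast(10, 0.4, 500, da, 1)
  p2 <- field_x_fast(10, 0.4, 500 + lam / 2, da, 1)
  dphi <- Arg(p2 / p1)
  expect_lt(abs(abs(dphi) - pi), 0.2)
})

test_that("displacement orders follow the ceiling rule", {
  expect_equal(choose_Dz0(10), 2L)
  expect_equal(choose_Dz0(0), 0L)
  expect_equal(choose_Dz0(20), 3L)
  expect_error(choose_Dz0(-1), "non-negative")
})

test_that("axial derivatives and displaced evaluation reuse the same array", {
  sys <- small_sys()
  k <- wavenumber_grid(sys)[9]
  g <- source_grid(70, 1000, 28, 190, D_z0 = 2)
  da <- derivative_array(g, sys, k = k)
  # n0 = 0 reduces to the plain surrogate
  expect_identical(axial_derivative_fast(17, 432, 0, da, 1),
                   taylor_h(17, 432, da, 1))
  # n0 = 1 against a central finite difference of the true h (the shifted
  # derivative series keeps all D_z + 1 terms, so it is closer to the true
  # derivative than a difference of the truncated surrogate)
  d <- 1e-3
  hp <- dwi_h_direct(17, 432 + d, wavenumber_grid(sys)[9], sys)
  hm <- dwi_h_direct(17, 432 - d, wavenumber_grid(sys)[9], sys)
  a1 <- axial_derivative_fast(17, 432, 1, da, 1)
  expect_lt(Mod(a1$h0 - (hp$h0 - hm$h0) / (2 * d)) / Mod(a1$h0), 1e-4)
  expect_lt(Mod(a1$h2 - (hp$h2 - hm$h2) / (2 * d)) / Mod(a1$h2), 1e-4)
  expect_error(axial_derivative_fast(17, 432, 3, da, 1), "exceeds")
  # delta = 0 is exactly the undisplaced surrogate
  expect_identical(displaced_h(17, 432, 0, da, 1), taylor_h(17, 432, da, 1))
  # displacement error decreases monotonically with D_z0
  delta <- 5
  truth <- taylor_h(17, 432 + delta, da, 1)
  errs <- vapply(0:2, function(d0)
    Mod(displaced_h(17, 432, delta, da, 1, D_z0 = d0)$h0 - truth$h0),
    numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("sequential displacement composition matches a single total displacement", {
  sys <- small_sys()
  k <- wavenumber_grid(sys)[9]
  g <- source_grid(70, 1000, 28, 190, D_z0 = 3)
  da <- derivative_array(g, sys, k = k)
  d1 <- 2; d2 <- 3
  one <- displaced_h(22, 610, d1 + d2, da, 1)
  # two-stage: shift every stored-order derivative by d1, then expand d2
  # about the shifted state; equal to the single step up to cross terms of
  # total order above D_z0
  D0 <- da$grid$D_z0
  two_h0 <- 0
  for (n0 in 0:D0) {
    deriv_at_d1 <- 0
    for (m0 in 0:(D0 - n0)) {
      deriv_at_d1 <- deriv_at_d1 + d1^m0 / factorial(m0) *
        axial_derivative_fast(22, 610, n0 + m0, da, 1)$h0
    }
    two_h0 <- two_h0 + d2^n0 / factorial(n0) * deriv_at_d1
  }
  expect_lt(Mod(one$h0 - two_h0) / Mod(one$h0), 1e-10)
})

test_that("derivative arrays persist with a configuration fingerprint", {
  sys <- small_sys()
  g <- source_grid(70, 400, 28, 190, D_rho = 3, D_z = 2)
  da <- derivative_array(g, sys, k = wavenumber_grid(sys)[c(1, 9)])
  path <- withr::local_tempfile(fileext = ".rds")
  save_derivative_array(da, path)
  back <- load_derivative_array(path)
  expect_identical(back$S, da$S)
  tampered <- readRDS(path)
  tampered$k <- tampered$k + 0.01
  saveRDS(tampered, path)
  expect_error(load_derivative_array(path), "fingerprint")
})
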