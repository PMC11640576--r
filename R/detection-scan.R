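# Interferogram formation and A-/B-/C-scan assembly. Any field backend can
# stand behind the sample-arm spectrum: the rigorous quadrature oracle, the
# Taylor engine over the full wavenumber grid, or Taylor + MSR where only
# the anchor fields are ever evaluated.

#' Spectral interferogram from the two modal coefficients
#'
#' `I(k) = |alpha_scat(k) + alpha_mirr(k)|^2`. The complex components are
#' retained so that phase-sensitive processing (the complex cross term) and
#' background subtraction remain available downstream.
#'
#' @param alpha_scat,alpha_mirr Complex vectors on the same wavenumber grid.
#' @param k_grid Wavenumbers (rad/um), uniform.
#' @return Object of class `interferogram`.
#' @export
make_interferogram <- function(alpha_scat, alpha_mirr, k_grid) {
  if (length(alpha_scat) != length(k_grid) ||
      length(alpha_mirr) != length(k_grid))
    stop("alpha_scat, alpha_mirr and k_grid must have equal length")
  out <- list(k_grid = k_grid, I = Mod(alpha_scat + alpha_mirr)^2,
              alpha_scat = alpha_scat, alpha_mirr = alpha_mirr)
  class(out) <- "interferogram"
  out
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf("<interferogram> %d wavenumbers, I in [%.3g, %.3g]\n",
              length(x$k_grid), min(x$I), max(x$I)))
  invisible(x)
}

#' Depth-resolved A-scan from an interferogram
#'
#' Inverse discrete Fourier transform of the spectrum over k. The
#' round-trip phase `exp(2 i eta k z)` of a reflector at depth `z` (relative
#' to the mirror plane) places its peak at depth bin
#' `z_p = p * pi / (eta * dk * N_pad)`, which defines the depth axis.
#'
#' Background handling:
#' \describe{
#'   \item{`"subtract"`}{transform `I - |alpha_mirr|^2 - |alpha_scat|^2`,
#'     i.e. the real cross term `2 Re(alpha_scat conj(alpha_mirr))` - the
#'     depth-resolved signal without DC and autocorrelation terms.}
#'   \item{`"complex"`}{transform the complex cross term
#'     `alpha_scat * conj(alpha_mirr)` - the phase-sensitive A-scan used for
#'     elastography processing (single-sided, no conjugate mirror image).}
#'   \item{`"raw"`}{transform `I` as detected.}
#' }
#'
#' @param ig An [make_interferogram()] object.
#' @param background One of `"subtract"`, `"complex"`, `"raw"`.
#' @param window `"none"` (default; the detection model prescribes no
#'   window) or `"hann"`.
#' @param pad Integer zero-padding factor (`>= 1`) for depth oversampling.
#' @param eta Refractive index used for the depth axis.
#' @return Object of class `ascan`: `z_axis` (um), complex `A`, pixel pitch
#'   `dz` and the processing metadata.
#' @export
make_ascan <- function(ig, background = c("subtract", "complex", "raw"),
                       window = c("none", "hann"), pad = 1L, eta = 1) {
  background <- match.arg(background)
  window <- match.arg(window)
  k <- ig$k_grid
  dks <- diff(k)
  if (length(k) < 2 || max(abs(dks - dks[1])) > 1e-8 * abs(dks[1]))
    stop("A-scan reconstruction requires a uniform wavenumber grid")
  y <- switch(background,
              raw = as.complex(ig$I),
              subtract = as.complex(ig$I - Mod(ig$alpha_mirr)^2 -
                                      Mod(ig$alpha_scat)^2),
              complex = ig$alpha_scat * Conj(ig$alpha_mirr))
  if (window == "hann") {
    n <- length(y)
    y <- y * 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  }
  pad <- as.integer(pad)
  stopifnot(pad >= 1L)
  npad <- pad * length(y)
  ypad <- c(y, complex(npad - length(y)))
  A <- stats::fft(ypad) / npad
  dz <- pi / (eta * dks[1] * npad)
  out <- list(z_axis = (seq_len(npad) - 1) * dz, A = A, dz = dz,
              background = background, window = window, pad = pad,
              eta = eta)
  class(out) <- "ascan"
  out
}

#' @export
print.ascan <- function(x, ...) {
  cat(sprintf(paste0("<ascan> %d depth bins, dz = %.3g um, range [0, %.4g] ",
                     "um, background = %s\n"),
              length(x$A), x$dz, max(x$z_axis), x$background))
  invisible(x)
}

# Sample-arm spectrum for one lateral beam position, any backend.
# scat is in the sample frame; (x0, y0) is the beam axis; scatterers beyond
# rho_max are dropped. delta (optional) are per-scatterer axial
# displacements applied via the backend's displacement path.
.alpha_scat_backend <- function(scat, sys, x0 = 0, y0 = 0, rho_max = 70,
                                backend = c("taylor_msr", "taylor",
                                            "rigorous"),
                                da = NULL, msr = NULL, nodes = 200,
                                delta = NULL) {
  backend <- match.arg(backend)
  nk <- sys$Nk
  xb <- scat$x - x0
  yb <- scat$y - y0
  rho <- sqrt(xb^2 + yb^2)
  keep <- which(rho <= rho_max & scat$rho_s > 0)
  if (length(keep) == 0L) return(complex(real = numeric(nk)))
  rho <- rho[keep]
  c2psi <- ifelse(rho > 0, (xb[keep]^2 - yb[keep]^2) / rho^2, 0)
  z <- scat$z[keep]
  rs <- scat$rho_s[keep]
  dl <- if (is.null(delta)) NULL else rep_len(delta, scat$Ns)[keep]
  if (backend == "rigorous") {
    zz <- if (is.null(dl)) z else z + dl
    sub <- scatterer_set(xb[keep], yb[keep], zz, rs)
    return(scat_modal_coefficient_rigorous(sub, sys, nodes = nodes))
  }
  if (is.null(da)) stop("fast backends need a derivative array: build one ",
                        "with derivative_array() (see also the fit-grid ",
                        "CLI subcommand)")
  prep <- .taylor_prep(da, rho, z)
  dz0 <- da$grid$D_z0
  field_at <- function(ik) {
    kk <- da$k[ik]
    if (is.null(dl)) {
      h <- .taylor_eval(da, prep, ik, 0L)
      zeff <- z
    } else {
      h <- .displaced_eval(da, prep, dl, ik, dz0)
      zeff <- z + dl
    }
    -1i * sys$f * kk * exp(1i * sys$eta * kk * (zeff - sys$zf)) *
      (h$h0 + c2psi * h$h2)
  }
  if (backend == "taylor") {
    if (length(da$k) != nk || max(abs(da$k - sys$k_grid)) > 1e-9)
      stop("the 'taylor' backend needs a derivative array over the full ",
           "wavenumber grid")
    return(vapply(seq_len(nk), function(ik) sum(rs * field_at(ik)^2),
                  complex(1)))
  }
  # taylor + MSR
  if (is.null(msr)) stop("the 'taylor_msr' backend needs an msr_model: fit ",
                         "one with msr_fit() (see also the fit-msr CLI ",
                         "subcommand)")
  if (length(da$k) != length(msr$kj) ||
      max(abs(da$k - msr$kj)) > 1e-9)
    stop("derivative array wavenumbers do not match the MSR anchors")
  E_anchors <- vapply(seq_along(msr$kj), field_at,
                      complex(length(rho)))
  if (length(rho) == 1L) E_anchors <- matrix(E_anchors, nrow = 1L)
  zeff <- if (is.null(dl)) z else z + dl
  ct <- cross_modal_table(E_anchors, rs, zeff, msr$D)
  msr_alpha_scat(ct, msr, sys)
}

#' Simulate the sample-arm spectrum and interferogram at one beam position
#'
#' Translates the scatterers into the beam frame, drops those beyond the
#' radial cutoff, evaluates `alpha_scat(k)` with the selected backend and
#' combines it with the (position-independent) mirror coefficient.
#'
#' @param scat A [scatterer_set()] in the sample frame.
#' @param sys An [optical_system()].
#' @param x0,y0 Beam-axis position (um).
#' @param rho_max Radial cutoff (um).
#' @param backend `"taylor_msr"`, `"taylor"` or `"rigorous"`.
#' @param da A [derivative_array()] (fast backends): over the full grid for
#'   `"taylor"`, over the MSR anchors for `"taylor_msr"`.
#' @param msr An [msr_fit()] model (`"taylor_msr"` only).
#' @param nodes Aperture quadrature nodes (rigorous backend and mirror).
#' @param alpha_mirr Optional precomputed mirror coefficient (complex vector
#'   over the grid); computed once here when `NULL`.
#' @param delta Optional per-scatterer axial displacements (um).
#' @return An [make_interferogram()] object.
#' @export
simulate_spectrum <- function(scat, sys, x0 = 0, y0 = 0, rho_max = 70,
                              backend = c("taylor_msr", "taylor",
                                          "rigorous"),
                              da = NULL, msr = NULL, nodes = 200,
                              alpha_mirr = NULL, delta = NULL) {
  backend <- match.arg(backend)
  if (is.null(alpha_mirr)) {
    alpha_mirr <- mirror_modal_coefficient(sys, nodes = nodes)
  }
  a_s <- .alpha_scat_backend(scat, sys, x0, y0, rho_max, backend, da, msr,
                             nodes, delta)
  make_interferogram(a_s, alpha_mirr, wavenumber_grid(sys))
}

#' Simulate a C-scan (or B-scan / single A-scan) over a lateral grid
#'
#' Runs [simulate_spectrum()] at every beam position of the scan geometry
#' and stacks the reconstructed A-scans. A 1 x 1 scan degenerates to a
#' single A-scan identical to the direct path.
#'
#' @param scat A [scatterer_set()] (sample frame).
#' @param scan A [scan_geometry()].
#' @param sys An [optical_system()].
#' @inheritParams simulate_spectrum
#' @param background,window,pad Passed to [make_ascan()]; the default
#'   complex cross term gives phase-sensitive A-scans.
#' @return Object of class `oct_cscan`: complex array `A` of shape
#'   `(n_x, n_y, n_depth)`, `z_axis`, the scan positions and backend
#'   metadata.
#' @export
simulate_cscan <- function(scat, scan, sys,
                           backend = c("taylor_msr", "taylor", "rigorous"),
                           da = NULL, msr = NULL, nodes = 200,
                           alpha_mirr = NULL, background = "complex",
                           window = "none", pad = 1L) {
  backend <- match.arg(backend)
  if (is.null(alpha_mirr))
    alpha_mirr <- mirror_modal_coefficient(sys, nodes = nodes)
  nx <- length(scan$x_positions); ny <- length(scan$y_positions)
  first <- TRUE
  A <- NULL; z_axis <- NULL
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    ig <- simulate_spectrum(scat, sys, scan$x_positions[ix],
                            scan$y_positions[iy], scan$rho_max, backend,
                            da, msr, nodes, alpha_mirr)
    asc <- make_ascan(ig, background = background, window = window,
                      pad = pad, eta = sys$eta)
    if (first) {
      A <- array(complex(1), c(nx, ny, length(asc$A)))
      z_axis <- asc$z_axis
      first <- FALSE
    }
    A[ix, iy, ] <- asc$A
  }
  out <- list(A = A, z_axis = z_axis, x_positions = scan$x_positions,
              y_positions = scan$y_positions, backend = backend,
              background = background, dz = z_axis[2] - z_axis[1])
  class(out) <- "oct_cscan"
  out
}

#' @export
print.oct_cscan <- function(x, ...) {
  d <- dim(x$A)
  cat(sprintf("<oct_cscan> %d x %d A-scans x %d depth bins (%s backend)\n",
              d[1], d[2], d[3], x$backend))
  invisible(x)
}

#' Normalised magnitude of a C-scan
#'
#' @param cs An `oct_cscan`.
#' @param normalize Divide by the global maximum (the convention used for
#'   display).
#' @return Numeric array of `|A|`, same shape as `cs$A`.
#' @export
cscan_magnitude <- function(cs, normalize = TRUE) {
  m <- Mod(cs$A)
  if (normalize && max(m) > 0) m <- m / max(m)
  m
}

#' Simulate a loaded series: one sample, many axial displacement fields
#'
#' Step 0 is the undisplaced sample; each subsequent load step displaces
#' every scatterer axially by the corresponding column of `displacements`
#' and re-simulates through the displacement expansion (no aperture
#' integral is re-evaluated; the anchor fields are re-assembled from the
#' same derivative array). The derivative array must have been built with
#' `D_z0 >= choose_Dz0(Ms)` where `Ms` is the maximum axial excursion.
#'
#' @param scat Base [scatterer_set()].
#' @param displacements Numeric `Ns x n_steps` matrix of axial displacements
#'   (um) relative to the base positions.
#' @param scan A [scan_geometry()].
#' @param sys An [optical_system()].
#' @inheritParams simulate_cscan
#' @param Ms Declared maximum displacement (um); steps exceeding it are an
#'   error (the series contract the derivative array was sized for).
#' @return List of `oct_cscan` objects, one per step (step 1 = unloaded).
#' @export
simulate_loaded_series <- function(scat, displacements, scan, sys,
                                   backend = c("taylor_msr", "taylor"),
                                   da = NULL, msr = NULL, nodes = 200,
                                   alpha_mirr = NULL, Ms = NULL,
                                   background = "complex", pad = 1L) {
  backend <- match.arg(backend)
  displacements <- as.matrix(displacements)
  if (nrow(displacements) != scat$Ns)
    stop("displacements must have one row per scatterer")
  if (is.null(Ms)) Ms <- max(abs(displacements))
  if (max(abs(displacements)) > Ms + 1e-12)
    stop("a displacement exceeds the declared maximum Ms = ", Ms, " um")
  if (!is.null(da) && da$grid$D_z0 < choose_Dz0(Ms))
    stop(sprintf(paste0("derivative array has D_z0 = %d but the declared ",
                        "displacement Ms = %g um needs D_z0 >= %d"),
                 da$grid$D_z0, Ms, choose_Dz0(Ms)))
  if (is.null(alpha_mirr))
    alpha_mirr <- mirror_modal_coefficient(sys, nodes = nodes)
  steps <- c(list(NULL), lapply(seq_len(ncol(displacements)),
                                function(d) displacements[, d]))
  lapply(steps, function(dl) {
    nx <- length(scan$x_positions); ny <- length(scan$y_positions)
    A <- NULL; z_axis <- NULL; first <- TRUE
    for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
      ig <- simulate_spectrum(scat, sys, scan$x_positions[ix],
                              scan$y_positions[iy], scan$rho_max, backend,
                              da, msr, nodes, alpha_mirr, delta = dl)
      asc <- make_ascan(ig, background = background, pad = pad,
                        eta = sys$eta)
      if (first) {
        A <- array(complex(1), c(nx, ny, length(asc$A)))
        z_axis <- asc$z_axis
        first <- FALSE
      }
      A[ix, iy, ] <- asc$A
    }
    out <- list(A = A, z_axis = z_axis, x_positions = scan$x_positions,
                y_positions = scan$y_positions, backend = backend,
                background = background, dz = z_axis[2] - z_axis[1])
    class(out) <- "oct_cscan"
    out
  })
}

#' Export C-scan magnitude as a multi-page TIFF
#'
#' One page per depth slice, magnitude normalised to the global maximum.
#' Requires the `tiff` package.
#'
#' @param cs An `oct_cscan`.
#' @param path Output file.
#' @export
write_cscan_tiff <- function(cs, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for TIFF export")
  m <- cscan_magnitude(cs, normalize = TRUE)
  pages <- lapply(seq_len(dim(m)[3]), function(i) m[, , i, drop = TRUE])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
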