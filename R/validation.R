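# Backend-comparison harness: the relative integral error metric, a
# rigorous-vs-fast comparison driver, and a demonstration phase-difference
# strain estimator for parameter-recovery checks.

#' Relative integral error between two arrays
#'
#' `Err(Fa) = sum |Fr - Fa|^2 / sum |Fr|^2` over all elements (plain sums:
#' uniform sampling is assumed; resample mixed-resolution data first). The
#' arrays may be complex fields, spectra, A-scans or whole C-scans; the
#' metric is invariant to a common complex scale.
#'
#' @param Fr Reference array (rigorous).
#' @param Fa Approximate array, same shape.
#' @return Non-negative scalar; 0 iff the arrays are identical.
#' @export
integral_error <- function(Fr, Fa) {
  if (!identical(dim(Fr), dim(Fa)) || length(Fr) != length(Fa))
    stop("arrays must have identical shape")
  den <- sum(Mod(Fr)^2)
  if (den == 0) stop("reference array is identically zero: error undefined")
  sum(Mod(Fr - Fa)^2) / den
}

#' Compare a fast backend against the rigorous oracle
#'
#' Simulates the same scan twice - once rigorously, once with the requested
#' fast backend - and reports the relative integral error of the complex
#' A-scans, overall and per A-scan (the per-position error profile).
#'
#' @param scat A [scatterer_set()] (sample frame).
#' @param sys An [optical_system()].
#' @param scan A [scan_geometry()].
#' @param backend Fast backend to test (`"taylor_msr"` or `"taylor"`).
#' @param da,msr Fast-backend artifacts (see [derivative_array()],
#'   [msr_fit()]).
#' @param U Error threshold the comparison is judged against.
#' @param nodes Aperture quadrature nodes for the rigorous path.
#' @param background A-scan mode compared (default complex cross term).
#' @return Object of class `error_report`: `err`, `per_ascan`, `pass`,
#'   `domain`, `n_points` and the compared backends.
#' @export
compare_backends <- function(scat, sys, scan, backend = "taylor_msr",
                             da = NULL, msr = NULL, U = 3e-4, nodes = 200,
                             background = "complex") {
  alpha_mirr <- mirror_modal_coefficient(sys, nodes = nodes)
  ref <- simulate_cscan(scat, scan, sys, backend = "rigorous",
                        nodes = nodes, alpha_mirr = alpha_mirr,
                        background = background)
  app <- simulate_cscan(scat, scan, sys, backend = backend, da = da,
                        msr = msr, alpha_mirr = alpha_mirr,
                        background = background)
  err <- integral_error(ref$A, app$A)
  nx <- dim(ref$A)[1]; ny <- dim(ref$A)[2]
  per <- matrix(NA_real_, nx, ny)
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    per[ix, iy] <- integral_error(ref$A[ix, iy, ], app$A[ix, iy, ])
  }
  dims <- sum(c(nx, ny) > 1) + 1L
  out <- list(err = err, per_ascan = per, pass = err <= U, U = U,
              domain = paste0(dims, "D"),
              n_points = length(ref$A),
              backends = c(reference = "rigorous", approximate = backend))
  class(out) <- "error_report"
  out
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(paste0("<error_report> %s vs %s on %s (%d samples): ",
                     "Err = %.3g (threshold %.3g) -> %s\n"),
              x$backends[["approximate"]], x$backends[["reference"]],
              x$domain, x$n_points, x$err, x$U,
              if (x$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Phase-difference strain estimator (demonstration)
#'
#' Estimates local axial strain from the phase difference between an
#' unloaded and a loaded complex A-scan of the same scatterers:
#' `phi(z) = arg(A_loaded * conj(A_unloaded))` advances by
#' `2 eta k_bar * dz(z)` for axial displacement `dz`, so under locally
#' uniform strain `e` the interferometric product `cr(z)` carries a phase
#' ramp `exp(2 i eta k_bar e z)`. The strain is estimated by a phase-ramp
#' matched filter: `e` maximising the amplitude-weighted coherence
#' `|sum_z cr(z) exp(-2 i eta k_bar e z)|` over the fit window (a coarse
#' candidate grid followed by local refinement). This is equivalent to an
#' amplitude-weighted fit of the phase slope but immune to phase wrapping,
#' which a 1-D profile cannot otherwise cross at dark pixels. Pixels where
#' the raw phase difference jumps by more than pi between neighbours are
#' reported as flagged. This is a deliberately simple estimator for
#' validating displacement fields; it is not a full elastography pipeline
#' (no 3-D unwrapping, no lateral regularisation).
#'
#' @param unloaded,loaded Complex A-scan vectors (same depth axis).
#' @param z_axis Depth axis (um).
#' @param k_bar Central wavenumber (rad/um).
#' @param eta Refractive index.
#' @param window Length-2 depth range (um) to fit over; `NULL` for all.
#' @param min_amp_frac Pixels with amplitude below this fraction of the
#'   window maximum get zero weight (they carry no usable phase).
#' @param strain_range Length-2 search interval for the strain.
#' @param n_candidates Coarse-grid size over `strain_range` (must sample
#'   the coherence peak, whose width is about `pi / (2 eta k_bar len)` for
#'   a window of length `len`).
#' @return List: `strain` (dimensionless), `coherence` (peak coherence,
#'   1 for a perfectly uniform ramp), `n_used`, `flagged` (window indices
#'   where the raw phase jumps by more than pi between adjacent pixels).
#' @export
phase_difference_strain <- function(unloaded, loaded, z_axis, k_bar,
                                    eta = 1, window = NULL,
                                    min_amp_frac = 0.05,
                                    strain_range = c(-0.02, 0.02),
                                    n_candidates = 2001) {
  stopifnot(length(unloaded) == length(loaded),
            length(z_axis) == length(unloaded))
  sel <- if (is.null(window)) seq_along(z_axis)
         else which(z_axis >= window[1] & z_axis <= window[2])
  if (length(sel) < 3) stop("fit window contains fewer than 3 pixels")
  z <- z_axis[sel]
  cr <- loaded[sel] * Conj(unloaded[sel])
  amp <- Mod(cr)
  flagged <- which(abs(diff(Arg(cr))) > pi)
  use <- amp >= min_amp_frac * max(amp)
  if (sum(use) < 3) stop("too few bright pixels in the fit window")
  z <- z[use]; cr <- cr[use]; amp <- amp[use]
  score <- function(e) {
    Mod(sum(cr * exp(-2i * eta * k_bar * e * z))) / sum(amp)
  }
  cand <- seq(strain_range[1], strain_range[2], length.out = n_candidates)
  s0 <- vapply(cand, score, numeric(1))
  i0 <- which.max(s0)
  half <- diff(strain_range) / (n_candidates - 1)
  opt <- stats::optimize(score, lower = cand[i0] - half,
                         upper = cand[i0] + half, maximum = TRUE,
                         tol = 1e-9)
  list(strain = opt$maximum, coherence = opt$objective,
       n_used = sum(use), flagged = sel[flagged])
}
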