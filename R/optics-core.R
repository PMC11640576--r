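#' Optical system description for a Fourier-domain OCT interferometer
#'
#' Bundles the objective, spectrum and reference-mirror parameters shared by
#' every simulation backend. All lengths are micrometres internally;
#' wavelengths are accepted in nanometres and converted. The illumination is
#' linearly polarised along x, with a Gaussian profile on the Gaussian
#' reference sphere, `exp(-(k*W)^2 sin^2(theta))`, so `W` controls the beam
#' waist (the 1/e amplitude waist radius at focus is approximately
#' `2*W/eta`).
#'
#' The wavenumber grid is uniform in k between `2*pi/lambda_max` and
#' `2*pi/lambda_min` (rad/um): the detected interferogram is inverse-Fourier
#' transformed over k, so uniform-in-k sampling is what the FFT requires.
#'
#' @param na Numerical aperture of the objective (dimensionless, `0 < na < eta`).
#' @param f Focal length of the objective (um). Scales field amplitude only.
#' @param eta Refractive index of the focal region.
#' @param W Gaussian apodization length (um).
#' @param lambda_min_nm,lambda_max_nm Spectral edges (nm).
#' @param Nk Number of wavenumber samples (uniform in k).
#' @param zf Focal-plane depth (um): the focal field is evaluated at `z - zf`.
#' @param mirror Reference mirror description from [mirror_spec()].
#' @param ez_cos_theta Logical; whether the common `cos(theta)` aperture factor
#'   multiplies the longitudinal (Ez) kernel. Ez never enters detection, so
#'   this only affects [focal_field_rigorous()] output for Ez.
#' @return An object of class `oct_system` with the derived wavenumber grid
#'   in `$k_grid` (rad/um, ascending).
#' @examples
#' sys <- optical_system(na = 0.1, lambda_min_nm = 1170, lambda_max_nm = 1408,
#'                       Nk = 64, zf = 300)
#' range(wavenumber_grid(sys))
#' @export
optical_system <- function(na = 0.1, f = 1e4, eta = 1, W = 2,
                           lambda_min_nm = 1170, lambda_max_nm = 1408,
                           Nk = 256, zf = 0, mirror = mirror_spec(),
                           ez_cos_theta = TRUE) {
  stopifnot(is.numeric(na), length(na) == 1L, is.finite(na))
  if (!(na > 0 && na < eta)) {
    stop("numerical aperture must satisfy 0 < na < eta (na = ", na,
         ", eta = ", eta, "): rays beyond the critical angle are evanescent")
  }
  if (!(lambda_min_nm > 0 && lambda_min_nm < lambda_max_nm)) {
    stop("spectral edges must satisfy 0 < lambda_min_nm < lambda_max_nm")
  }
  if (Nk < 2) stop("Nk must be at least 2 to form a spectrum")
  if (!(W > 0)) stop("apodization length W must be positive")
  if (!(f > 0)) stop("focal length f must be positive")
  k_min <- 2 * pi / (lambda_max_nm / 1000)   # rad/um
  k_max <- 2 * pi / (lambda_min_nm / 1000)
  sys <- list(na = na, f = f, eta = eta, W = W,
              lambda_min_nm = lambda_min_nm, lambda_max_nm = lambda_max_nm,
              Nk = as.integer(Nk), zf = zf, mirror = mirror,
              ez_cos_theta = isTRUE(ez_cos_theta),
              k_grid = seq(k_min, k_max, length.out = Nk))
  class(sys) <- "oct_system"
  sys
}

#' Reference mirror of the interferometer
#'
#' The reference-arm modal coefficient is a Riemann sum of the squared
#' incident field over a uniform square grid on the mirror plane.
#'
#' @param z_mirr Mirror plane depth (um). Defines zero optical path
#'   difference: depths in A-scans are measured from `z_mirr`.
#' @param rho_mirr Mirror reflectivity (dimensionless).
#' @param n Grid points per axis (odd recommended so the axis is sampled).
#' @param half_width Half-width of the square grid (um), or `NULL` to use
#'   4 beam waists at the mirror plane (waist evaluated at the central
#'   wavenumber, Gaussian-beam divergence).
#' @return An object of class `oct_mirror`.
#' @export
mirror_spec <- function(z_mirr = 0, rho_mirr = 1, n = 65L, half_width = NULL) {
  stopifnot(rho_mirr >= 0, n >= 2)
  m <- list(z_mirr = z_mirr, rho_mirr = rho_mirr, n = as.integer(n),
            half_width = half_width)
  class(m) <- "oct_mirror"
  m
}

#' @export
print.oct_system <- function(x, ...) {
  cat("<oct_system>\n")
  cat(sprintf("  NA = %.3g, eta = %.3g, f = %.4g um, W = %.3g um, zf = %.4g um\n",
              x$na, x$eta, x$f, x$W, x$zf))
  cat(sprintf("  spectrum: [%.0f, %.0f] nm, Nk = %d (k in [%.4f, %.4f] rad/um)\n",
              x$lambda_min_nm, x$lambda_max_nm, x$Nk,
              min(x$k_grid), max(x$k_grid)))
  cat(sprintf("  mirror: z = %.4g um, reflectivity = %.3g, grid %dx%d\n",
              x$mirror$z_mirr, x$mirror$rho_mirr, x$mirror$n, x$mirror$n))
  invisible(x)
}

#' Wavenumber grid of an optical system
#'
#' @param sys An [optical_system()].
#' @return Numeric vector of `Nk` wavenumbers (rad/um), uniform, ascending.
#' @export
wavenumber_grid <- function(sys) sys$k_grid

#' Set of discrete point scatterers
#'
#' Positions are in the sample frame (z = 0 at the surface, increasing into
#' the sample); `rho_s` is the scattering cross-section weight of each
#' scatterer, so the dipole field it radiates is `rho_s` times the incident
#' field at its position.
#'
#' @param x,y,z Coordinates (um), equal length.
#' @param rho_s Cross-section weights, all `>= 0`. Recycled if scalar.
#' @return Object of class `scatterer_set` (a list of the four vectors plus
#'   the count `Ns`).
#' @export
scatterer_set <- function(x, y, z, rho_s = 1) {
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    stop("x, y, z must have equal length")
  }
  rho_s <- rep_len(rho_s, n)
  if (n > 0 && (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z))))
    stop("scatterer coordinates must be finite")
  if (any(rho_s < 0)) stop("rho_s must be non-negative")
  out <- list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
              rho_s = as.numeric(rho_s), Ns = n)
  class(out) <- "scatterer_set"
  out
}

#' @export
print.scatterer_set <- function(x, ...) {
  cat(sprintf("<scatterer_set> Ns = %d", x$Ns))
  if (x$Ns > 0) {
    cat(sprintf(", z in [%.4g, %.4g] um, sum(rho_s) = %.4g",
                min(x$z), max(x$z), sum(x$rho_s)))
  }
  cat("\n")
  invisible(x)
}

#' Lateral scan geometry
#'
#' Lateral scanning is implemented by shifting scatterer (x, y) coordinates
#' relative to the beam axis, which is equivalent to translating the beam.
#' Scatterers further than `rho_max` from the beam axis are excluded from an
#' A-scan: the focused beam carries negligible energy there.
#'
#' @param x_positions,y_positions Beam-axis positions (um).
#' @param rho_max Radial cutoff (um), positive.
#' @return Object of class `scan_geometry`.
#' @export
scan_geometry <- function(x_positions = 0, y_positions = 0, rho_max = 70) {
  stopifnot(rho_max > 0, all(is.finite(x_positions)), all(is.finite(y_positions)))
  out <- list(x_positions = as.numeric(x_positions),
              y_positions = as.numeric(y_positions),
              rho_max = rho_max)
  class(out) <- "scan_geometry"
  out
}

#' Minimum wavenumber count satisfying the Nyquist depth-sampling rule
#'
#' The inverse FFT of the spectrum maps depth `z_max` unambiguously only if
#' the fringe `exp(2i eta k z)` of the deepest reflector is sampled at two
#' points per cycle: `Nk >= ceil(2 eta z_max (k_max - k_min) / pi)`.
#'
#' @param sys An [optical_system()].
#' @param z_max Deepest scatterer depth relative to the mirror plane (um).
#' @return Integer minimum `Nk`.
#' @export
nyquist_nk <- function(sys, z_max) {
  dk_span <- max(sys$k_grid) - min(sys$k_grid)
  as.integer(ceiling(2 * sys$eta * z_max * dk_span / pi))
}

#' Validate a simulation configuration
#'
#' Checks the joint invariants of system, scan geometry and domain: aperture
#' below the medium index, ordered spectrum, positive extents, and the
#' Nyquist rule on `Nk` (see [nyquist_nk()]). Sub-Nyquist spectra alias deep
#' scatterers and are rejected unless explicitly allowed (aliasing is
#' harmless when, e.g., two backends are compared on identical grids).
#'
#' @param sys An [optical_system()].
#' @param scan A [scan_geometry()].
#' @param z_max Axial extent of the scatterer domain (um).
#' @param allow_sub_nyquist Logical; permit `Nk` below the Nyquist bound.
#' @return Invisibly, a list with the validated pieces and `nk_min`.
#' @export
validate_config <- function(sys, scan, z_max, allow_sub_nyquist = FALSE) {
  stopifnot(inherits(sys, "oct_system"), inherits(scan, "scan_geometry"))
  if (!(z_max > 0)) stop("z_max must be positive")
  nk_min <- nyquist_nk(sys, z_max)
  if (sys$Nk < nk_min && !allow_sub_nyquist) {
    stop(sprintf(paste0(
      "Nk = %d is below the Nyquist bound for z_max = %g um: at least %d ",
      "wavenumbers are required to sample the deepest fringe ",
      "(set allow_sub_nyquist = TRUE to override)"), sys$Nk, z_max, nk_min))
  }
  invisible(list(sys = sys, scan = scan, z_max = z_max, nk_min = nk_min))
}

# ---- configuration / table I/O ------------------------------------------

#' Read or write a flat key-value configuration file
#'
#' Format: one `key = value` per line, `#` comments allowed. Units are
#' mandatory in key names (`lambda_min_nm`, `z_max_um`, ...). Recognised
#' keys: `na`, `f_um`, `eta`, `w_um`, `lambda_min_nm`, `lambda_max_nm`,
#' `n_k`, `zf_um`, `z_mirr_um`, `rho_mirr`, `mirror_n`, `mirror_half_width_um`,
#' `rho_max_um`, `z_max_um`, plus approximation keys `d_rho`, `d_z`, `d_z0`,
#' `s_rho_um`, `s_z_um`, `msr_l`, `msr_d_um`. Depths given in mm are accepted
#' through `*_mm` variants and converted.
#'
#' @param path File path.
#' @return `read_oct_config`: a named list with `sys` ([optical_system()]),
#'   `scan` ([scan_geometry()]), `z_max` and `approx` (approximation
#'   parameters). `write_oct_config`: the path, invisibly.
#' @export
read_oct_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (any(is.na(vals))) stop("non-numeric config value(s) for: ",
                             paste(keys[is.na(vals)], collapse = ", "))
  cfg <- stats::setNames(as.list(vals), keys)
  um <- function(key_um, key_mm, default) {
    if (!is.null(cfg[[key_um]])) cfg[[key_um]]
    else if (!is.null(cfg[[key_mm]])) cfg[[key_mm]] * 1000
    else default
  }
  grab <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  mirror <- mirror_spec(
    z_mirr = um("z_mirr_um", "z_mirr_mm", 0),
    rho_mirr = grab("rho_mirr", 1),
    n = as.integer(grab("mirror_n", 65)),
    half_width = if (!is.null(cfg$mirror_half_width_um)) cfg$mirror_half_width_um else NULL)
  sys <- optical_system(
    na = grab("na", 0.1), f = um("f_um", "f_mm", 1e4), eta = grab("eta", 1),
    W = um("w_um", "w_mm", 2),
    lambda_min_nm = grab("lambda_min_nm", 1170),
    lambda_max_nm = grab("lambda_max_nm", 1408),
    Nk = as.integer(grab("n_k", 256)), zf = um("zf_um", "zf_mm", 0),
    mirror = mirror)
  scan <- scan_geometry(rho_max = um("rho_max_um", "rho_max_mm", 70))
  approx <- list(d_rho = as.integer(grab("d_rho", 20)),
                 d_z = as.integer(grab("d_z", 8)),
                 d_z0 = as.integer(grab("d_z0", 0)),
                 s_rho = um("s_rho_um", "s_rho_mm", 28),
                 s_z = um("s_z_um", "s_z_mm", 190),
                 msr_l = as.integer(grab("msr_l", 35)),
                 msr_d = um("msr_d_um", "msr_d_mm", 15))
  list(sys = sys, scan = scan, z_max = um("z_max_um", "z_max_mm", 1000),
       approx = approx)
}

#' @rdname read_oct_config
#' @param cfg A list as returned by `read_oct_config`.
#' @export
write_oct_config <- function(cfg, path) {
  sys <- cfg$sys
  lines <- c(
    sprintf("na = %.17g", sys$na),
    sprintf("f_um = %.17g", sys$f),
    sprintf("eta = %.17g", sys$eta),
    sprintf("w_um = %.17g", sys$W),
    sprintf("lambda_min_nm = %.17g", sys$lambda_min_nm),
    sprintf("lambda_max_nm = %.17g", sys$lambda_max_nm),
    sprintf("n_k = %d", sys$Nk),
    sprintf("zf_um = %.17g", sys$zf),
    sprintf("z_mirr_um = %.17g", sys$mirror$z_mirr),
    sprintf("rho_mirr = %.17g", sys$mirror$rho_mirr),
    sprintf("mirror_n = %d", sys$mirror$n),
    if (!is.null(sys$mirror$half_width))
      sprintf("mirror_half_width_um = %.17g", sys$mirror$half_width),
    sprintf("rho_max_um = %.17g", cfg$scan$rho_max),
    sprintf("z_max_um = %.17g", cfg$z_max),
    sprintf("d_rho = %d", cfg$approx$d_rho),
    sprintf("d_z = %d", cfg$approx$d_z),
    sprintf("d_z0 = %d", cfg$approx$d_z0),
    sprintf("s_rho_um = %.17g", cfg$approx$s_rho),
    sprintf("s_z_um = %.17g", cfg$approx$s_z),
    sprintf("msr_l = %d", cfg$approx$msr_l),
    sprintf("msr_d_um = %.17g", cfg$approx$msr_d))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a scatterer table (CSV)
#'
#' Delimited text with mandatory header `x_um,y_um,z_um,rho_s`.
#'
#' @param path File path.
#' @return A [scatterer_set()].
#' @export
read_scatterers <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_um", "y_um", "z_um", "rho_s")
  if (!all(need %in% names(df))) {
    stop("scatterer table must have columns ", paste(need, collapse = ", "))
  }
  scatterer_set(df$x_um, df$y_um, df$z_um, df$rho_s)
}

#' @rdname read_scatterers
#' @param scat A [scatterer_set()].
#' @export
write_scatterers <- function(scat, path) {
  df <- data.frame(x_um = scat$x, y_um = scat$y, z_um = scat$z,
                   rho_s = scat$rho_s)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# beam 1/e amplitude radius at axial distance dz from focus (central k)
.beam_waist_at <- function(sys, dz) {
  k_bar <- mean(range(sys$k_grid))
  w0 <- 2 * sys$W / sys$eta
  zr <- sys$eta * k_bar * w0^2 / 2
  w0 * sqrt(1 + (dz / zr)^2)
}
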