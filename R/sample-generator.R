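# Synthetic scatterer phantoms and axial displacement fields: uniform
# random clouds at speckle-forming density, heterogeneous-reflectivity
# regions, uniform strain and a stiff elliptic-cylinder inclusion.

#' Uniform random scatterer phantom in a box
#'
#' Positions are i.i.d. uniform over the box; the default density
#' `3.90625e-3 um^-3` is the reference speckle-forming density (many
#' scatterers per resolution volume, so the complex signal is a circular
#' Gaussian sum and its magnitude Rayleigh-distributed). Cross-sections are
#' constant by default; a depth profile models signal attenuation; region
#' multipliers model heterogeneous reflectivity.
#'
#' @param x_range,y_range,z_range Box extents (um), length-2 vectors.
#' @param n Scatterer count; when `NULL`, `round(volume * density)`.
#' @param density Number density (um^-3), used when `n` is `NULL`.
#' @param seed Integer seed; generation is deterministic given the seed and
#'   does not disturb the caller's RNG state.
#' @param rho_s Base cross-section weight.
#' @param rho_s_fun Optional function of depth `z` returning a multiplier
#'   (signal attenuation profile).
#' @param regions Optional list of regions, each a list with `x_range`,
#'   `y_range`, `z_range` and `multiplier`: scatterers inside get their
#'   `rho_s` multiplied (applied cumulatively in order).
#' @return A [scatterer_set()].
#' @export
generate_uniform_phantom <- function(x_range = c(0, 200),
                                     y_range = c(0, 200),
                                     z_range = c(0, 1000),
                                     n = NULL, density = 0.00390625,
                                     seed = 1, rho_s = 1,
                                     rho_s_fun = NULL, regions = NULL) {
  vol <- diff(x_range) * diff(y_range) * diff(z_range)
  if (vol <= 0) stop("phantom volume must be positive")
  if (is.null(n)) n <- round(vol * density)
  n <- as.integer(n)
  if (n == 0L) return(scatterer_set(numeric(0), numeric(0), numeric(0),
                                    numeric(0)))
  pos <- withr::with_seed(seed, {
    list(x = stats::runif(n, x_range[1], x_range[2]),
         y = stats::runif(n, y_range[1], y_range[2]),
         z = stats::runif(n, z_range[1], z_range[2]))
  })
  w <- rep_len(rho_s, n)
  if (!is.null(rho_s_fun)) w <- w * rho_s_fun(pos$z)
  for (rg in regions) {
    inside <- pos$x >= rg$x_range[1] & pos$x <= rg$x_range[2] &
      pos$y >= rg$y_range[1] & pos$y <= rg$y_range[2] &
      pos$z >= rg$z_range[1] & pos$z <= rg$z_range[2]
    w[inside] <- w[inside] * rg$multiplier
  }
  scatterer_set(pos$x, pos$y, pos$z, w)
}

#' Uniform random phantom in a cylinder around the beam axis
#'
#' Area-uniform in the disc of radius `rho_max` (so the radial density
#' matches the box phantom), uniform in depth. Convenient for single
#' A-scan experiments where only scatterers within the radial cutoff
#' matter.
#'
#' @param rho_max Disc radius (um).
#' @param z_range Depth extent (um).
#' @param n Scatterer count.
#' @param seed Integer seed.
#' @param rho_s Cross-section weight(s).
#' @return A [scatterer_set()] centered on the beam axis.
#' @export
generate_disc_phantom <- function(rho_max = 70, z_range = c(0, 1000),
                                  n = 500, seed = 1, rho_s = 1) {
  stopifnot(rho_max > 0, n >= 0)
  if (n == 0L) return(scatterer_set(numeric(0), numeric(0), numeric(0),
                                    numeric(0)))
  withr::with_seed(seed, {
    r <- rho_max * sqrt(stats::runif(n))
    phi <- stats::runif(n, 0, 2 * pi)
    z <- stats::runif(n, z_range[1], z_range[2])
    scatterer_set(r * cos(phi), r * sin(phi), z, rho_s)
  })
}

#' Apply a uniform axial strain
#'
#' Compression convention: `z -> z (1 + strain)` with negative strain
#' moving scatterers toward the surface. Lateral coordinates and
#' cross-sections are unchanged.
#'
#' @param scat A [scatterer_set()].
#' @param strain Dimensionless strain (millistrain = 1e-3); magnitude
#'   capped at 0.05, beyond which the small-deformation model is not
#'   meaningful.
#' @return A [scatterer_set()] with extra fields `displacement` (the
#'   per-scatterer axial displacement, um) and `Ms` (its maximum absolute
#'   value, um).
#' @export
apply_uniform_strain <- function(scat, strain) {
  if (abs(strain) > 0.05)
    stop("|strain| above 0.05 is outside the supported range")
  dz <- scat$z * strain
  out <- scatterer_set(scat$x, scat$y, scat$z + dz, scat$rho_s)
  out$displacement <- dz
  out$Ms <- if (scat$Ns) max(abs(dz)) else 0
  out
}

#' Apply the piecewise strain of a stiff elliptic-cylinder inclusion
#'
#' The inclusion is an elliptic cylinder extending through the volume along
#' y: its cross-section in the (x, z) plane is the ellipse
#' `((x - x0)/ax)^2 + ((z - z0)/az)^2 <= 1`. Axial strain is `strain_in`
#' inside and `strain_out` outside; the axial displacement integrates the
#' strain along each A-line from the surface downward,
#' `dz(z) = integral_0^z eps(x, zeta) dzeta`, so it is continuous across
#' the inclusion boundary and reduces to [apply_uniform_strain()] when the
#' two strains coincide. Lateral coupling (shear) is intentionally not
#' modelled: the deformation is axial-only, as appropriate for coupling to
#' an external mechanical model when more is needed.
#'
#' @param scat A [scatterer_set()].
#' @param center `c(x0, z0)` of the ellipse (um).
#' @param semi_axes `c(ax, az)` semi-axes (um), positive.
#' @param strain_in,strain_out Strains inside / outside (magnitudes capped
#'   at 0.05).
#' @return As [apply_uniform_strain()]: displaced set with `displacement`
#'   and `Ms`.
#' @export
apply_inclusion_strain <- function(scat, center, semi_axes, strain_in,
                                   strain_out) {
  stopifnot(length(center) == 2, length(semi_axes) == 2,
            all(semi_axes > 0))
  if (max(abs(c(strain_in, strain_out))) > 0.05)
    stop("|strain| above 0.05 is outside the supported range")
  dz <- inclusion_displacement(scat$x, scat$z, center, semi_axes,
                               strain_in, strain_out)
  out <- scatterer_set(scat$x, scat$y, scat$z + dz, scat$rho_s)
  out$displacement <- dz
  out$Ms <- if (scat$Ns) max(abs(dz)) else 0
  out
}

#' @describeIn apply_inclusion_strain The displacement field itself:
#'   `dz(x, z)` for arbitrary coordinates (used to compare recovered
#'   strains against the generating field).
#' @param x,z Coordinates (um).
#' @export
inclusion_displacement <- function(x, z, center, semi_axes, strain_in,
                                   strain_out) {
  n <- max(length(x), length(z))
  x <- rep_len(x, n); z <- rep_len(z, n)
  u <- (x - center[1]) / semi_axes[1]
  # chord of the ellipse along z at this x, clipped to [0, z]
  half <- ifelse(abs(u) <= 1, semi_axes[2] * sqrt(pmax(1 - u^2, 0)), 0)
  lo <- center[2] - half
  hi <- center[2] + half
  inside_len <- pmax(pmin(z, hi) - pmax(0, lo), 0) * (half > 0)
  strain_out * (z - inside_len) + strain_in * inside_len
}
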