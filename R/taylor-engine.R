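# Fast evaluation of the phase-factored focal field by Taylor expansion
# about a sparse source-point grid. The slow radial integrals h0, h2 (see
# dwi_h_direct) and their mixed radial/axial derivatives are computed once,
# at a few source points, by analytic differentiation under the integral
# sign; the field at every scatterer then follows from polynomial
# evaluation. An additional axial expansion re-uses the same derivative
# array to displace scatterers axially without re-evaluating any integral.

#' Build a sparse source-point grid
#'
#' Source points are cell centers: `rho_j = (j - 1/2) s_rho` for
#' `j = 1..ceil(rho_max/s_rho)` and likewise in z, so every point of the
#' covered domain is within half a spacing of its nearest source point.
#'
#' @param rho_max,z_max Radial and axial extents to cover (um).
#' @param s_rho,s_z Source spacings (um).
#' @param D_rho,D_z Highest radial and axial derivative orders retained.
#' @param D_z0 Additional axial orders for the displacement expansion
#'   (see [choose_Dz0()]); the derivative array then stores axial orders up
#'   to `D_z + D_z0`.
#' @return An object of class `source_grid`.
#' @examples
#' g <- source_grid(70, 1000, 28, 190)
#' c(g$N_rho, g$N_z)   # 3, 6
#' @export
source_grid <- function(rho_max, z_max, s_rho = 28, s_z = 190,
                        D_rho = 20, D_z = 8, D_z0 = 0) {
  stopifnot(rho_max > 0, z_max > 0, s_rho > 0, s_z > 0,
            D_rho >= 0, D_z >= 0, D_z0 >= 0)
  N_rho <- as.integer(ceiling(rho_max / s_rho))
  N_z <- as.integer(ceiling(z_max / s_z))
  g <- list(rho_max = rho_max, z_max = z_max, s_rho = s_rho, s_z = s_z,
            D_rho = as.integer(D_rho), D_z = as.integer(D_z),
            D_z0 = as.integer(D_z0),
            N_rho = N_rho, N_z = N_z,
            rho_sources = (seq_len(N_rho) - 0.5) * s_rho,
            z_sources = (seq_len(N_z) - 0.5) * s_z)
  class(g) <- "source_grid"
  g
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf(paste0("<source_grid> %d x %d sources over [0, %g] x [0, %g] um",
                     " (s_rho = %g, s_z = %g)\n"),
              x$N_rho, x$N_z, x$N_rho * x$s_rho, x$N_z * x$s_z,
              x$s_rho, x$s_z))
  cat(sprintf("  orders: D_rho = %d, D_z = %d, D_z0 = %d\n",
              x$D_rho, x$D_z, x$D_z0))
  invisible(x)
}

#' Storage budget of a derivative array
#'
#' The number of aperture integrals held is
#' `(D_rho + 1) * (D_z + 1) * N_rho * N_z * Nk` (the displacement orders
#' `D_z0` add proportionally).
#'
#' @param grid A [source_grid()].
#' @param Nk Number of wavenumbers the array is built for.
#' @return List with `n_tot` (integral count at the base orders), `n_stored`
#'   (including `D_z0`) and `bytes` (complex storage for both field
#'   components).
#' @export
taylor_budget <- function(grid, Nk) {
  n_tot <- (grid$D_rho + 1) * (grid$D_z + 1) * grid$N_rho * grid$N_z * Nk
  n_stored <- (grid$D_rho + 1) * (grid$D_z + grid$D_z0 + 1) *
    grid$N_rho * grid$N_z * Nk
  list(n_tot = n_tot, n_stored = n_stored, bytes = 2 * 16 * n_stored)
}

#' Additional axial orders needed for a given maximum displacement
#'
#' Axial displacement by `delta` is evaluated through a second Taylor
#' expansion of order `D_z0`; `D_z0 = ceiling(0.15 * Ms)` keeps the
#' end-to-end error below the package's reference accuracy threshold, where
#' `Ms` is the maximum axial excursion (um) of any scatterer across the
#' simulated load steps.
#'
#' @param Ms Maximum axial displacement (um), non-negative.
#' @return Integer order (0 when `Ms = 0`).
#' @export
choose_Dz0 <- function(Ms) {
  if (length(Ms) != 1L || !is.finite(Ms) || Ms < 0)
    stop("Ms must be a single non-negative displacement in um")
  as.integer(ceiling(0.15 * Ms))
}

# J_c^(m)(x) rows via the derivative identity
# J_c^(m) = 2^-m * sum_{i=0}^m (-1)^i choose(m, i) J_{c - m + 2i}
# jtab: (max_order + 1) x Q matrix of J_0..J_max at the nodes
.bessel_deriv_row <- function(jtab, c, m) {
  acc <- 0
  for (i in 0:m) {
    o <- c - m + 2L * i
    row <- if (o >= 0) jtab[o + 1L, ] else (-1)^((-o) %% 2) * jtab[-o + 1L, ]
    acc <- acc + (-1)^(i %% 2) * choose(m, i) * row
  }
  acc / 2^m
}

#' Compute the derivative array S at the source points
#'
#' For each field component `c` in `{0, 2}`, source point `(rho_j, z_l)` and
#' wavenumber, stores the mixed derivatives
#' `d^(m+n) h_c / d rho^m d z^n` for `m = 0..D_rho`,
#' `n = 0..D_z + D_z0`. Differentiation is analytic under the integral
#' sign: each axial order multiplies the kernel by
#' `(i eta k (cos t - 1))`, each radial order by `(eta k sin t)` with the
#' Bessel factor replaced by its derivative (binomial identity over
#' neighbouring orders); the resulting one-dimensional integrals are
#' evaluated by Gauss-Legendre quadrature.
#'
#' @param grid A [source_grid()].
#' @param sys An [optical_system()].
#' @param k Wavenumbers to store (rad/um): the full grid for a pure Taylor
#'   backend, or the MSR anchor subset.
#' @param k_index Optional integer indices of `k` within
#'   `wavenumber_grid(sys)` (kept as metadata).
#' @param nodes Aperture quadrature nodes.
#' @return An object of class `derivative_array`: list with the complex
#'   array `S` of dimension `(2, D_rho+1, D_z+D_z0+1, N_rho, N_z,
#'   length(k))` (component order `h0`, `h2`), plus `grid`, `sys`, `k`,
#'   `k_index`.
#' @export
derivative_array <- function(grid, sys, k = wavenumber_grid(sys),
                             k_index = NULL, nodes = 200) {
  stopifnot(inherits(grid, "source_grid"), inherits(sys, "oct_system"),
            length(k) >= 1)
  ap <- .aperture_nodes(sys, nodes)
  M <- grid$D_rho + 1L
  Nn <- grid$D_z + grid$D_z0 + 1L
  nk <- length(k)
  S <- array(complex(1), dim = c(2L, M, Nn, grid$N_rho, grid$N_z, nk))
  g0 <- ap$ct * ap$st * (1 + ap$ct)
  g2 <- ap$ct * ap$st * (ap$ct - 1)
  max_ord <- grid$D_rho + 2L
  for (ik in seq_len(nk)) {
    kk <- k[ik]
    apod <- exp(-(kk * sys$W)^2 * ap$st^2)
    rate_r <- sys$eta * kk * ap$st          # radial derivative rate
    rate_z <- 1i * sys$eta * kk * (ap$ct - 1)  # axial derivative rate
    # axial factor matrix: Nn x Q, cumulative powers
    ax <- matrix(complex(1), Nn, nodes)
    ax[1L, ] <- 1
    if (Nn > 1L) for (n in 2:Nn) ax[n, ] <- ax[n - 1L, ] * rate_z
    for (j in seq_len(grid$N_rho)) {
      x <- rate_r * grid$rho_sources[j]
      jtab <- t(vapply(0:max_ord, function(o) besselJ(x, o),
                       numeric(nodes)))
      R0 <- matrix(0, M, nodes)
      R2 <- matrix(0, M, nodes)
      pow <- rep(1, nodes)
      for (m in 0:grid$D_rho) {
        R0[m + 1L, ] <- pow * .bessel_deriv_row(jtab, 0L, m)
        R2[m + 1L, ] <- pow * .bessel_deriv_row(jtab, 2L, m)
        pow <- pow * rate_r
      }
      for (l in seq_len(grid$N_z)) {
        zeta <- grid$z_sources[l] - sys$zf
        base <- ap$w * apod * exp(1i * sys$eta * kk * zeta * (ap$ct - 1))
        S[1L, , , j, l, ik] <- (R0 * matrix(g0 * base, M, nodes, byrow = TRUE)) %*% t(ax)
        S[2L, , , j, l, ik] <- (R2 * matrix(g2 * base, M, nodes, byrow = TRUE)) %*% t(ax)
      }
    }
  }
  if (any(!is.finite(Re(S))) || any(!is.finite(Im(S))))
    stop("derivative array contains non-finite entries")
  out <- list(S = S, grid = grid, sys = sys, k = k,
              k_index = if (is.null(k_index)) seq_along(k) else as.integer(k_index),
              nodes = nodes)
  class(out) <- "derivative_array"
  out
}

#' @export
print.derivative_array <- function(x, ...) {
  d <- dim(x$S)
  cat(sprintf(paste0("<derivative_array> S[%s] at %d wavenumbers ",
                     "(%.1f MB)\n"),
              paste(d, collapse = " x "), length(x$k),
              16 * prod(d) / 2^20))
  print(x$grid)
  invisible(x)
}

# Nearest-source-cell assignment; ties at cell boundaries go to the lower
# index. Errors on points outside the covered domain (no extrapolation).
.cell_index <- function(v, spacing, n, what) {
  tol <- 1e-9 * spacing
  if (any(v < -tol) || any(v > n * spacing + tol))
    stop(sprintf("%s coordinate outside the source-grid domain [0, %g]",
                 what, n * spacing))
  pmin(pmax(ceiling(v / spacing), 1L), n)
}

# Precompute per-point grouping and polynomial-offset matrices (independent
# of wavenumber, so a scan over k amortises this).
.taylor_prep <- function(da, rho, z) {
  g <- da$grid
  n <- max(length(rho), length(z))
  rho <- rep_len(rho, n); z <- rep_len(z, n)
  j0 <- .cell_index(rho, g$s_rho, g$N_rho, "radial")
  l0 <- .cell_index(z, g$s_z, g$N_z, "axial")
  cell <- (l0 - 1L) * g$N_rho + j0
  groups <- split(seq_len(n), cell)
  M <- g$D_rho + 1L
  Nz1 <- g$D_z + 1L
  prep <- lapply(groups, function(idx) {
    jj <- j0[idx[1L]]; ll <- l0[idx[1L]]
    dr <- rho[idx] - g$rho_sources[jj]
    dz <- z[idx] - g$z_sources[ll]
    Pm <- matrix(1, length(idx), M)
    if (M > 1L) for (m in 1:(M - 1L)) Pm[, m + 1L] <- Pm[, m] * dr / m
    Zn <- matrix(1, length(idx), Nz1)
    if (Nz1 > 1L) for (nn in 1:(Nz1 - 1L)) Zn[, nn + 1L] <- Zn[, nn] * dz / nn
    list(idx = idx, j = jj, l = ll, Pm = Pm, Zn = Zn)
  })
  list(n = n, groups = prep)
}

# Evaluate the order-n0 axial derivative of the Taylor surrogate hT at the
# prepared points for wavenumber index ik. Returns list(h0, h2).
.taylor_eval <- function(da, prep, ik, n0 = 0L) {
  g <- da$grid
  if (n0 > g$D_z0)
    stop(sprintf("axial derivative order %d exceeds the stored D_z0 = %d",
                 n0, g$D_z0))
  cols <- (n0 + 1L):(n0 + g$D_z + 1L)
  h0 <- h2 <- complex(prep$n)
  for (gr in prep$groups) {
    S0 <- matrix(da$S[1L, , , gr$j, gr$l, ik], g$D_rho + 1L)[, cols, drop = FALSE]
    S2 <- matrix(da$S[2L, , , gr$j, gr$l, ik], g$D_rho + 1L)[, cols, drop = FALSE]
    h0[gr$idx] <- rowSums((gr$Pm %*% S0) * gr$Zn)
    h2[gr$idx] <- rowSums((gr$Pm %*% S2) * gr$Zn)
  }
  list(h0 = h0, h2 = h2)
}

#' Taylor-expanded field components at arbitrary points
#'
#' Evaluates the Taylor surrogate `hT` of the phase-factored radial
#' integrals about the nearest source point (ties at cell boundaries break
#' toward the lower index).
#'
#' @param rho,z Cylindrical radius and sample-frame depth (um), vectors.
#' @param da A [derivative_array()].
#' @param k_index Index into `da$k` selecting the wavenumber.
#' @return List of complex vectors `h0`, `h2`.
#' @export
taylor_h <- function(rho, z, da, k_index = 1L) {
  .taylor_eval(da, .taylor_prep(da, rho, z), k_index, 0L)
}

#' @describeIn taylor_h Order-`n0` axial derivative of the surrogate
#'   (index-shifted sum over the same array; `n0 = 0` reduces to
#'   `taylor_h`). Requires `n0 <= D_z0` of the grid.
#' @param n0 Axial derivative order.
#' @export
axial_derivative_fast <- function(rho, z, n0, da, k_index = 1L) {
  .taylor_eval(da, .taylor_prep(da, rho, z), k_index, as.integer(n0))
}

# displaced h via the secondary axial expansion, shared core
.displaced_eval <- function(da, prep, delta, ik, D_z0) {
  h <- .taylor_eval(da, prep, ik, 0L)
  if (D_z0 > 0L) {
    wgt <- rep_len(1, prep$n)
    for (n0 in 1:D_z0) {
      wgt <- wgt * delta / n0
      dh <- .taylor_eval(da, prep, ik, n0)
      h$h0 <- h$h0 + wgt * dh$h0
      h$h2 <- h$h2 + wgt * dh$h2
    }
  }
  h
}

#' Field components after axial displacement, without re-integration
#'
#' Approximates `h(rho, z + delta; k)` by a second Taylor expansion in the
#' axial offset `delta`, of order `D_z0`, whose derivative terms are
#' themselves evaluated from the stored array (see
#' [axial_derivative_fast()]). With `D_z0 = 0` this is identical to
#' [taylor_h()] at the undisplaced point.
#'
#' @inheritParams taylor_h
#' @param delta Axial displacements (um), per point (recycled).
#' @param D_z0 Expansion order; defaults to the grid's `D_z0`.
#' @return List of complex vectors `h0`, `h2` at `(rho, z + delta)`.
#' @export
displaced_h <- function(rho, z, delta, da, k_index = 1L,
                        D_z0 = da$grid$D_z0) {
  prep <- .taylor_prep(da, rho, z)
  .displaced_eval(da, prep, rep_len(delta, prep$n), k_index, as.integer(D_z0))
}

#' Fast x-component of the incident field
#'
#' Composes the Taylor surrogate into the field:
#' `Ex = -i f k exp(i eta k (z - zf)) (h0 + cos(2 psi) h2)`. The azimuthal
#' dependence sits entirely outside the Taylor machinery. With `delta`
#' supplied, evaluates the axially displaced field (the factored phase is
#' displaced too: `exp(i eta k (z + delta - zf))`).
#'
#' @inheritParams taylor_h
#' @param psi Azimuths from the polarisation axis (rad).
#' @param delta Optional axial displacements (um).
#' @param D_z0 Displacement expansion order (only with `delta`).
#' @return Complex vector `Ex`.
#' @export
field_x_fast <- function(rho, psi, z, da, k_index = 1L, delta = NULL,
                         D_z0 = da$grid$D_z0) {
  n <- max(length(rho), length(psi), length(z))
  rho <- rep_len(rho, n); psi <- rep_len(psi, n); z <- rep_len(z, n)
  sys <- da$sys
  kk <- da$k[k_index]
  if (is.null(delta)) {
    h <- taylor_h(rho, z, da, k_index)
    zeff <- z
  } else {
    delta <- rep_len(delta, n)
    h <- displaced_h(rho, z, delta, da, k_index, D_z0)
    zeff <- z + delta
  }
  -1i * sys$f * kk * exp(1i * sys$eta * kk * (zeff - sys$zf)) *
    (h$h0 + cos(2 * psi) * h$h2)
}

#' Persist / restore a derivative array
#'
#' Derivative arrays are expensive relative to the scans that reuse them, so
#' C-scan jobs can store them keyed by configuration. Serialisation uses R's
#' native RDS format with a configuration fingerprint that is checked on
#' load.
#'
#' @param da A [derivative_array()].
#' @param path File path (`.rds`).
#' @export
save_derivative_array <- function(da, path) {
  da$fingerprint <- .config_fingerprint(da)
  saveRDS(da, path)
  invisible(path)
}

#' @rdname save_derivative_array
#' @export
load_derivative_array <- function(path) {
  da <- readRDS(path)
  if (!inherits(da, "derivative_array"))
    stop("file does not contain a derivative array")
  fp <- da$fingerprint
  da$fingerprint <- NULL
  if (!identical(fp, .config_fingerprint(da)))
    stop("derivative array fingerprint mismatch: file was built for a different configuration")
  da
}

.config_fingerprint <- function(da) {
  x <- da[c("grid", "k", "nodes")]
  x$sys <- da$sys[c("na", "f", "eta", "W", "lambda_min_nm", "lambda_max_nm",
                    "Nk", "zf")]
  paste(format(unlist(x), digits = 15), collapse = "|")
}
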