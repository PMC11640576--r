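# Shared fixtures, built lazily and cached for the whole test run. The
# expensive objects (the reference-arm coefficient over 256 wavenumbers,
# MSR fits, derivative arrays) are reused across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

# standard full-depth configuration: reference spectrum, mid-depth focus
acc_sys <- function() fixture("acc_sys", function() {
  optical_system(na = 0.1, f = 1e4, eta = 1, W = 2,
                 lambda_min_nm = 1170, lambda_max_nm = 1408,
                 Nk = 256, zf = 500)
})

acc_msr <- function() fixture("acc_msr", function() {
  msr_fit(acc_sys(), L = 35, D = 15, rho_max = 70, z_max = 1000)
})

acc_mirror <- function() fixture("acc_mirror", function() {
  mirror_modal_coefficient(acc_sys())
})

# anchor-wavenumber derivative array at the recommended orders, with two
# displacement orders so strain scenarios up to ~13 um excursion reuse it
acc_da <- function() fixture("acc_da", function() {
  m <- acc_msr()
  g <- source_grid(70, 1000, 28, 190, D_rho = 20, D_z = 8, D_z0 = 2)
  derivative_array(g, acc_sys(), k = m$kj, k_index = m$anchor_idx)
})

# small, fast configuration for unit-level checks
small_sys <- function(Nk = 16, zf = 0, W = 2, ...) {
  optical_system(na = 0.1, f = 1e4, eta = 1, W = W,
                 lambda_min_nm = 1170, lambda_max_nm = 1408,
                 Nk = Nk, zf = zf, ...)
}

# relative difference helpers
rel_err <- function(a, b) max(Mod(a - b)) / max(Mod(b))
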