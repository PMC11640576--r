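---
title: "Image formation in octsim: model, approximations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image formation in octsim: model, approximations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(octsim)
```

## The detection model

octsim simulates spectrometer-based Fourier-domain OCT of samples made of
discrete point scatterers. For each wavenumber $k$ the detector records

$$I(k) = \lVert \alpha_{scat}(k) + \alpha_{mirr}(k) \rVert^2, \qquad
  A(z) = \mathcal{F}^{-1}\{I(k)\}(2z),$$

where $\alpha_{scat}$ and $\alpha_{mirr}$ are the modal coefficients of the
sample and reference arms: overlap integrals of the back-coupled fields
with the fiber mode. Under the first-order Born approximation each
scatterer radiates as a dipole driven by the incident field, and because
detection and illumination share the same optics the sample-arm
coefficient collapses to

$$\alpha_{scat}(k) = \sum_{s=1}^{N_s} \rho_s \,
  \left(E^{inc}_x(x_s, y_s, z_s; k)\right)^2 ,$$

with $\rho_s \ge 0$ the scattering cross-section weight. The reference arm
is a Riemann sum of the same squared field over a uniform grid on the
mirror plane. The model is noiseless and dispersion-free by construction:
single scattering only, linear-x input polarisation, no detector or shot
noise, no spectrometer roll-off.

The incident field is the focal field of an aplanatic objective with a
Gaussian pupil profile $\exp(-(kW)^2 \sin^2\theta)$, given by the
Debye-Wolf diffraction integral. After azimuthal integration the three
Cartesian components reduce to single integrals over the aperture angle
$\theta \in [0, \arcsin(NA/\eta)]$ with $J_0$, $J_1$, $J_2$ Bessel
kernels; `focal_field_rigorous()` evaluates that reduced form by
Gauss-Legendre quadrature, and `focal_field_aperture()` keeps the full 2-D
aperture integral (no Bessel functions) as an independent oracle for it.
The test suite holds the two within $10^{-6}$ of each other.

Only the $x$ component enters detection. It separates as

$$E_x = -ifk\, e^{i\eta k (z - z_f)}\,
  \bigl(h_0(\rho, z; k) + \cos(2\psi)\, h_2(\rho, z; k)\bigr),$$

where $h_0$ and $h_2$ are aperture integrals with kernels
$\cos\theta\sin\theta(1 + \cos\theta) J_0$ and
$\cos\theta\sin\theta(\cos\theta - 1) J_2$ and the *slow* axial phase
$e^{i\eta k (z - z_f)(\cos\theta - 1)}$. Factoring the fast carrier
$e^{i\eta k (z - z_f)}$ out of the integral is the step that makes $h$
smooth enough for polynomial approximation. The printed form of the
longitudinal ($E_z$) row is ambiguous about whether the common
$\cos\theta$ factor multiplies it; both variants are available behind
`ez_cos_theta` (default `TRUE`), and the choice is irrelevant to
detection, which uses $E_x$ only.

## Acceleration 1: Taylor expansion about source points

Evaluating the quadrature at every scatterer and wavenumber is the cost
bottleneck. octsim instead computes $h_0, h_2$ *and their mixed
derivatives* $\partial^{m+n} h_c / \partial\rho^m \partial z^n$ at a
sparse grid of source points $(\rho_j^s, z_l^s)$ - derivatives obtained by
analytic differentiation under the integral sign (each axial order
multiplies the kernel by $i\eta k(\cos\theta - 1)$, each radial order by
$\eta k \sin\theta$ with the Bessel factor replaced through the binomial
derivative identity) - and evaluates the field anywhere by the Taylor
polynomial about the nearest source point. The complex array
`derivative_array()` holds
$(D_\rho + 1)(D_z + D_{z0} + 1) N_\rho N_z N_k$ integrals per component.

Recommended orders, validated end to end by the acceptance suite:
$D_\rho = 20$, $D_z = 8$ with spacings $s_\rho = 28$ um, $s_z = 190$ um,
which cover a 70 um x 1 mm domain with $N_\rho = 3$, $N_z = 6$ sources.
At these settings the relative integral error of a fast A-scan against
the rigorous quadrature is below $10^{-6}$ on the package's reduced
instances - comfortably inside the reference accuracy threshold
$U = 3\times 10^{-4}$ used throughout the tests.

A second, nested expansion handles axially displaced scatterers (the
elastography workflow): the axial derivatives of the surrogate itself are
index-shifted sums over the same array, so a loaded scan re-uses every
stored integral. The extra axial orders required grow with the maximum
displacement as $D_{z0} = \lceil 0.15\, M_s \rceil$ with $M_s$ in um
(`choose_Dz0()`); each derivative keeps the full $D_z + 1$ axial terms, so
the stored axial orders extend to $D_z + D_{z0}$.

Numerical choices in this engine:

* **Quadrature**: fixed 200-node Gauss-Legendre over the aperture angle.
  At NA 0.1 and 1 mm depth the integrand carries only a few oscillation
  cycles, and node-doubling changes results by less than $10^{-9}$
  relative (asserted in tests). A `check_convergence` flag exposes the
  node-doubling diagnostic at evaluation time.
* **Nearest-source ties** break toward the lower index, so outputs are
  deterministic and reproducible bit for bit.
* **Summation**: the polynomial is evaluated as a factorial-weighted
  bilinear form with cumulative-product weights
  ($w_{m+1} = w_m \Delta\rho / (m+1)$), which never forms a bare
  factorial or power and is overflow-free at order 20; source-point
  exactness and finite-difference agreement are asserted to $10^{-5}$.
* **Radial origin**: the Bessel-identity rows are regular at $\rho = 0$
  via $J_{-n} = (-1)^n J_n$; no special-casing.
* **Out-of-domain points** raise an error; the engine never extrapolates
  silently.

## Acceleration 2: multi-spectral regression (MSR)

The aperture integrand at any point is a superposition of elementary
functions $d\, e^{-a^2 k^2} e^{i b k}$ whose parameters do not depend on
$k$. MSR fits coefficient functions $C_j(k)$, $j = 1..L$, such that

$$e^{-\alpha^2 k^2} e^{i\beta k} \approx \sum_j C_j(k)\,
  e^{-\alpha^2 k_j^2} e^{i\beta k_j}$$

holds over $\alpha \in [0, W\,NA/\eta]$ and $|\beta| \le B$; the same
combination then maps the *fields* at $L$ anchor wavenumbers to any $k$ in
the spectrum. Re-centering each scatterer on its 15 um depth band keeps
the phase argument inside the fitted window; the band geometry enters the
bound

$$B = \rho_{max} NA + z_{max} NA^2/\eta + \eta D / 2 ,$$

which evaluates to 24.5 um at the standard configuration. (The defocus
term admits a second reading with $2\eta$ in the denominator - a
small-angle bound on $1 - \cos$ - giving 19.5 um; both are implemented in
`compute_bound_B()` and the larger, default reading is the conservative
choice: a wider fitted phase window can only help.)

With the bands in place, the whole sample collapses into cross-modal
tables $\alpha_{cross}(j_1, j_2, h) = \sum_{s \in band\,h} \rho_s E_x(P_s;
k_{j_1}) E_x(P_s; k_{j_2})$ and the spectrum at *every* wavenumber is
assembled from them - the per-wavenumber cost no longer scales with the
number of scatterers.

Fitting: the residual is linear in the complex coefficients, so each
wavenumber's fit is an ordinary least-squares problem. The anchor family
is severely collinear (design-matrix singular values span ~15 orders of
magnitude), so the solver is a rank-revealing SVD pseudo-inverse
(relative cutoff $10^{-10}$) returning the minimum-norm solution -
deterministic, so refits are bit-identical; the `seed` argument exists
only for interface uniformity. The training grid is 32 points in
$\alpha$ times 129 in $\beta$, with a twice-denser held-out grid scoring
the fit; at $L = 35$ anchors over the standard spectrum the held-out
residual is ~$5\times10^{-9}$, far below what the end-to-end error budget
needs. A residual above $10^{-3}$ records a warning but still returns the
model.

## Scans, depth axis and phase-sensitive output

`make_ascan()` inverse-transforms the spectrum with no window and no
padding by default (the detection model prescribes none; Hann and integer
padding are flags). Depth bin $p$ maps to
$z_p = p\,\pi / (\eta\, \Delta k_{step} N_{pad})$, with zero optical path
at the mirror plane. Three backgrounds are supported: `subtract`
(removes $|\alpha_{mirr}|^2$ and $|\alpha_{scat}|^2$, keeping the real
cross term), `complex` (the complex cross term
$\alpha_{scat}\overline{\alpha_{mirr}}$ - the phase-sensitive A-scan,
free of the conjugate mirror image) and `raw`. Lateral scanning shifts
scatterer coordinates relative to the beam axis, excluding scatterers
beyond `rho_max` = 70 um, where the squared focal field is below
$10^{-3}$ of its on-axis value. C-scan magnitudes are conventionally
displayed normalised to the volume's global maximum
(`cscan_magnitude()`).

The wavenumber count must satisfy the depth Nyquist rule
$N_k \ge \lceil 2\eta z_{max}\Delta k/\pi \rceil$; `validate_config()`
enforces it with an explicit override flag, since backend-comparison
experiments on identical sub-Nyquist grids alias both backends equally
and remain valid.

## Synthetic phantoms and displacement fields

`generate_uniform_phantom()` draws i.i.d. uniform scatterer positions at
the reference speckle-forming density $3.90625\times10^{-3}$ um$^{-3}$,
with optional depth-attenuation profiles and region-wise cross-section
multipliers (heterogeneous reflectivity). `generate_disc_phantom()` is
the cylindrical variant for single-A-scan experiments. Displacement
fields: uniform axial strain ($z \to z(1+\hat\epsilon)$, negative =
compression, toward the surface) and a stiff elliptic-cylinder inclusion
whose piecewise-constant strain is integrated along each A-line from the
surface downward, so the displacement is continuous across the inclusion
boundary and reduces exactly to the uniform law when the two strains
coincide. The integration origin at the sample surface is the package's
choice (the natural one for a free surface); lateral/shear coupling is
deliberately not modelled - the generator emulates axial-only
deformation, and mechanically consistent 3-D fields are expected to come
from an external mechanical model.

What passing tests on these phantoms do *not* show about real data:
tissue is not a set of independent point dipoles at uniform density;
there is no multiple scattering, no refractive-index continuum, no noise
floor, and the displacement fields ignore lateral strain. The phantoms
validate the *image-formation pipeline*, not tissue realism.

## The demonstration strain estimator

`phase_difference_strain()` recovers axial strain from the phase of
$cr(z) = A_{loaded}\overline{A_{unloaded}}$, which advances by
$2\eta\bar{k}\,\delta z(z)$. A 1-D profile cannot be reliably unwrapped
across dark speckle gaps, so instead of regressing unwrapped phase the
estimator maximises the amplitude-weighted coherence
$|\sum_z cr(z) e^{-2i\eta\bar{k}\,e\,z}|$ over candidate strains $e$
(coarse grid of 2001 candidates over $\pm 20$ millistrain, then local
refinement) - algebraically a weighted phase-slope fit, but wrap-immune.
Pixels below 5% of the window's peak amplitude are excluded; raw
adjacent-pixel jumps above $\pi$ are reported as flagged. Recovery on the
package's fixtures is within a few percent at 0.5-3 millistrain and
degrades (~15% at 10 millistrain) as displacements approach the axial
resolution and speckle decorrelates - which is physics, not estimator
failure. This is a validation tool; published weighted-least-squares
elastography pipelines with 3-D unwrapping are out of scope and only
recovery quality, not method equivalence, is claimed.

## Speckle statistics experiment

"Fully developed" speckle (circular-Gaussian field, Rayleigh magnitude)
requires several scatterers per resolution cell. At the reference density
the cell occupancy is set by the beam: a 2 um apodization length (4 um
waist) yields of order one scatterer per cell and visibly heavy-tailed
statistics, while the instrument class the default spectrum mimics has
~11 um waists. The speckle test therefore uses $W = 5.5$ um, whose large
Rayleigh range also flattens the focal envelope across the sampled band,
plus Hann-apodized reconstruction (suppressing axial sinc sidelobes and
widening the coherence cell). Problem size: a 348 x 348 x 140 um phantom
(~66k scatterers), 14 x 14 A-scans at 16 um pitch (one beam waist and a
half, near-independent samples), every third depth bin across a 100 um
band around focus, intensities normalised per depth bin - 1960 pixels
tested against a unit-mean exponential law by Kolmogorov-Smirnov at the
0.01 level, with a fixed seed.

## Problem sizes and persistence

The validation and acceptance experiments run at desk scale by design:
256 wavenumbers, hundreds of scatterers for rigorous-vs-fast comparisons
(the rigorous path costs minutes; the fast path milliseconds), and C-scan
statistics from a few hundred A-scans. The same code paths scale to the
full-size scenarios (865 wavenumbers, $3\times10^5$ scatterers, 40000
A-scans per C-scan) - the arithmetic of those sizes is checked exactly,
and `taylor_budget()` reports the storage they need. Derivative arrays
and MSR models persist as RDS files with a configuration fingerprint
checked on load (`save_derivative_array()`); C-scan magnitudes export to
multi-page TIFF, scatterer tables and probed fields to CSV.

## Known limitations

* Single scattering only; no speckle decorrelation from multiple
  scattering, no attenuation except through user-supplied $\rho_s(z)$
  profiles.
* Linear-x input polarisation; other states would need new kernel rows.
* Displacements are axial-only in the fast path; arbitrary 3-D motion
  requires rebuilding the lateral part (rigorous backend handles it by
  re-evaluation).
* The mirror coefficient is a Riemann sum whose accuracy floors near
  $10^{-5}$ relative for practical grids (truncation vs. resolution); it
  is a common factor across backends and cancels in comparisons.
* The strain demo estimator assumes locally uniform strain inside the
  fit window and degrades once displacements approach the axial
  resolution.
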