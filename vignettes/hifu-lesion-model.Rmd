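---
title: "Modelling HIFU thermal lesions in the presence of boiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HIFU thermal lesions in the presence of boiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hifusim)
```

High-intensity focused ultrasound (HIFU) ablates tissue by concentrating an
ultrasound beam until the focal region coagulates. When the focus exceeds
the boiling temperature, a vapor bubble cloud forms that reflects most of
the incident beam, reshaping the heat deposition and hence the lesion. No
tractable acoustic solver simulates that scattering directly, so `hifusim`
couples a deterministic acoustic-thermal pipeline to a phenomenological
*equivalent model* of the bubble cloud. This vignette explains each stage,
the parameters that matter, the numerical choices, and what the package's
tests do and do not demonstrate.

## The acoustic stage

The reference transducer is a 3-MHz spherical cap (curvature radius 38 mm,
aperture 56 mm, f-number 0.68) with a rectangular cutout for a confocal
imaging probe. The built-in beam stage discretizes the cap into surface
elements (projected pitch one third of a wavelength; the surface pitch is
checked against the half-wavelength limit) and sums the monochromatic
point-source kernel $e^{ikr}/r$ over elements, with straight-ray per-layer
phase speed and amplitude attenuation through the water / superficial
tissue / liver stack. The source amplitude is set so the radiated power
matches the requested acoustic power through the plane-wave impedance
relation. Two implementation details are worth knowing:

* **Velocity is computed analytically.** The time-averaged intensity
  $\mathbf I = \tfrac12\,\mathrm{Re}(p\,\mathbf v^*)$ needs the particle
  velocity $\mathbf v = \nabla p /(i\omega\rho)$. At 200 µm spacing a
  3-MHz field has barely 2.4 samples per wavelength, where
  finite-difference gradients underestimate $|\nabla p|$ severely, so the
  beam stage accumulates the exact kernel gradient during the summation.
  The finite-difference operator (`intensity_from_pressure()`) remains
  available for imported fields that resolve the wavelength.
* **A fast evaluation path.** The hole-free cap is axisymmetric, so its
  field is evaluated on an $(r, z)$ table by ring quadrature (azimuthal
  midpoint rule with the node count adapted to the phase spread, which is
  spectrally accurate for periodic integrands) and spline-interpolated onto
  the lattice; the cutout patch is then subtracted by direct summation on
  one lateral quadrant and mirrored. The fast path is validated against
  the direct double-precision summation in the test suite (agreement to
  about 0.1 % of the focal peak), and the direct path against the
  closed-form on-axis solution for a focused cap.

Nonlinear propagation is **not** simulated. Shocked HIFU beams deposit
extra power near the focus and lose power to harmonic absorption before
it; in the modelling tradition this package follows, that enhancement is
folded into the calibrated absorption ratio (below). An import path
(`import_field()`) accepts an externally computed complex pressure volume
(for example from a nonlinear solver) as a NIfTI pair with a JSON sidecar.
The hole dimensions are not published for the reference device; the
default is 20 mm x 8 mm (long side along the imaging-probe axis) and is
configurable.

## From field to heat source

The plane-wave estimate $Q_{\mathrm{PW}} = 2\alpha_{\mathrm{att}} I$ with
$I = |p|^2/(2\rho c)$ is accurate where the beam is quasi-planar, and the
divergence form $-\nabla\cdot\mathbf I$ is exact but numerically produces
negative values in focused beams (it is exposed as a diagnostic only). The
working formulation is *energy conserving*: the acoustic power $P(z)$
crossing each transverse plane is computed as the plane integral of $I_z$
plus the accumulated side-face fluxes, so that $-dP/dz$ is exactly the
power absorbed per unit depth inside the computational box; each layer's
loss is then spread over its plane proportionally to $|p|^2$. Two
numerical choices:

* The layer losses are differences of $P$ interpolated at half-planes
  (centered differences in the interior), which makes the total deposited
  power telescope *exactly* to $P(z_{\min}) - P(z_{\max})$. Layers with an
  artefactual negative loss are clipped to zero and the clipped power is
  recorded.
* On the 14 mm-wide reference grid the converging cone partially enters
  through the side faces, which offsets the raw side-corrected profile by
  a constant. The profile is therefore anchored at the focal plane, where
  the beam is laterally contained and the plane integral alone is the
  crossing power. For a beam contained at every depth the anchor is a
  no-op. This matters only for the *interpretation* of $P(z)$ (used by the
  boiling model's intercepted power); the heat source depends on $dP/dz$
  alone.

Only a fraction $A = \alpha_{\mathrm{abs}}/\alpha_{\mathrm{att}}$ of the
lost power becomes heat. Literature values for liver disagree by a factor
of two, and $A$ also absorbs the nonlinear enhancement, so it is a
calibrated parameter (reference value 0.37). Finally the source is blurred
in each transverse plane by a 2-D Gaussian of standard deviation
$\sigma_{\mathrm{defoc}}$ (reference value 290 µm), modelling
heterogeneity-induced defocusing; the kernel is truncated at $4\sigma$ and
renormalized, so per-plane power is preserved away from the lateral
boundaries. Focus trajectories are simple lateral translations of the
source (bilinear for sub-voxel offsets); translated sources are cached per
offset, and the default trajectory period is one revolution per second
(the reference device's value is unpublished).

## The thermal model

Temperature obeys a generalized Pennes equation,
$$\rho_t C_t(T)\,\partial_t T = k_t \nabla^2 T +
\omega_b(D)\,\rho_b C_b (T_b - T) + Q,$$
integrated with an explicit Euler step and a 7-point centered Laplacian,
Dirichlet $T = 37\,^\circ$C on all faces (the heated region is far from
the boundaries at the reference grid size). Three generalizations matter:

* **Temperature-dependent specific heat.** $C_t(T) = C_0 +
  C_{\mathrm{denat}}(T) + C_{\mathrm{boil}}(T)$ keeps the solver from
  overestimating temperature: protein denaturation consumes 22 kJ/kg and
  the progressive vaporization of the 75 % water fraction consumes
  $0.75 \times 2260$ kJ/kg between 37 and 140 °C. The published source
  profiles are calorimetric curves that are not reproduced numerically
  here; both are modelled as truncated Gaussian bumps (denaturation
  centered at 60 °C, sd 6 °C; vaporization centered at 100 °C, sd 12 °C)
  rescaled so the *integral constraints* hold to 0.1 % — the integrals,
  not the shapes, are the tested contract. The bump is evaluated through a
  0.05-K lookup table inside the compiled stepper and the table is checked
  against the R definition in the tests.
* **Dose-dependent perfusion.** $\omega_b(D) = \max(1 - D/14400, 0)\,
  \omega_b(0)$: once the local microvasculature has received the
  destruction dose it no longer cools. Blood parameters are not published
  for the reference study; defaults are $\rho_b = 1050$ kg/m³, $C_b =
  3800$ J kg⁻¹ K⁻¹, $T_b = 37$ °C, configurable.
* **Thermal dose.** CEM43 is accumulated as $D \mathrel{+}= \Delta t\,
  0.5^{(43 - T)}$ with the post-step temperature at every step, heating
  and cooling alike. The conventional slope change below 43 °C is *not*
  applied — the single-exponent form is used deliberately, for fidelity to
  the model being reproduced. Lesions are voxels with $D \ge 14.4\times
  10^3$ s; sizes are bounding-box extents of the largest 6-connected
  component.

The explicit scheme is stable for $\Delta t \le \rho C_0 \Delta x^2 /
(6 k_t)$, which is 0.0447 s for liver at 200 µm. The reference time step
of 0.05 s slightly exceeds that nominal limit (the rising $C_t(T)$ relaxes
it at high temperature, which likely explains its stability in practice);
the package defaults to 0.04 s and warns, rather than errors, when a
configured step exceeds the limit.

## The boiling equivalent model

Whenever any voxel exceeds $T_{\mathrm{boil}} = 85$ °C (consistent with
the onset of the vaporization bump), the source is rebuilt each step:

1. the cloud $\mathcal B = \{T > T_{\mathrm{boil}}\}$ receives no heat at
   all (that energy is spent on mechanical and thermal damage);
2. a shielding coefficient $r_{\mathrm{shield}}$ is the maximum over
   planes of the fraction of deposited power intercepted by
   $\mathcal B$, reached at plane $z_{\mathrm{shield}}$ (most proximal
   plane on ties);
3. the enhanced zone $\mathcal H$ is the dilation of $\mathcal B$ by a
   voxelized ball of radius $R_{SE} = 2.5$ mm;
4. a power $P_{\mathcal H} = \eta_{\mathrm{intercept}}\, r_{\mathrm{shield}}\,
   P(z_{\mathrm{shield}})$ (with $\eta_{\mathrm{intercept}} = 0.31$) is
   deposited on $\mathcal H \setminus \mathcal B$ with weights
   $W_1 W_2 W_3$: inverse distance to the cloud; 1 before versus
   $r_{\mathrm{shield}}$ beyond the shielding plane; and either the
   undisturbed source (cloud top locally convex) or a uniform field
   boosted by $W_+ = 10$ inside a cone of half-aperture $\pi/18$ pointing
   from the instantaneous focus toward the transducer (cloud top locally
   concave). Convexity is decided by whether the cloud's most proximal
   voxel lies on the focal column.

Design points decided here: the redistributed power lives on $\mathcal H
\setminus \mathcal B$, not all of $\mathcal H$, since heating is null
inside the cloud; it is *added* to the cloud-zeroed base source rather
than replacing it (an optional flag additionally attenuates the base
source beyond the shielding plane by $1 - r_{\mathrm{shield}}$, off by
default); $W_1$ distances are in voxel units (the scale cancels in the
normalization); and the cone and focal column follow the instantaneous
focus during trajectories. The normalization makes $\sum Q_{\mathrm{boil}}
\Delta x^3 = P_{\mathcal H}$ exact at every step. Residual bubble clouds
from *previous* pulses are deliberately not modelled: within a treatment,
each new pulse re-detects boiling from the temperature field alone.

## Calibration and analysis

`calibrate_A_sigma()` implements the two-stage logic used to fix $A$ and
$\sigma_{\mathrm{defoc}}$: the absorption ratio shifts every onset while
defocusing mostly delays stationary pulses (a moving focus already
spreads the energy), so the routine alternates 1-D bisections — $\sigma$
against the stationary-pulse onset target, then $A$ against the
moving-pulse target — until both onsets match within tolerance (0.05 s by
default; the moving target defaults to 8.1 s, the experimental median).
Monotonicity is exercised by the test suite on a coarse synthetic
configuration; full-grid calibration is expensive and is left to users
via the command-line `calibrate` entry point.

`deming_regression()` fits lesion size against boiling onset time with an
errors-in-variables line (onset uncertainty about 0.1 s, size about
0.1 mm), minimizing $\sum (y - a - bx)^2/(s_y^2 + b^2 s_x^2)$ with the
closed-form Deming estimator and a seeded nonparametric bootstrap for the
90 % confidence interval. `slope_experiment()` generates the
size-versus-onset pairs by perturbing $\sigma_{\mathrm{defoc}}$ (±25 % by
default) around its reference value — the mechanism chosen because onset
variability in comparable experiments is attributed to slight local
defocusing — and reports one slope per axis, negative when later boiling
gives smaller lesions.

## The synthetic beam and what the tests show

`synthetic_focal_beam()` is a first-class generator of analytic test
fields: a separable Gaussian pressure envelope with plane-wave axial
intensity and optional cumulative attenuation. It emulates the focal
region of a real beam — a smooth, laterally compact hot spot with a known
closed-form power profile — which is exactly what the heat-source,
thermal, boiling and calibration machinery consume. It does **not**
emulate prefocal lobes, the cutout's asymmetry, side-entering flux, or
any nonlinearity; tests that depend on those properties use the Rayleigh
stage itself. Consequently, green pulse-level tests on synthetic beams
demonstrate the correctness of the *thermal and boiling machinery* under
controlled inputs, not the realism of any particular beam.

The coarse configurations used by the property tests run on a
31 x 31 x 41 grid at 500 µm with $\Delta t = 0.25$ s; the reproduction
scenarios use the full 71 x 71 x 111 grid at 200 µm with $\Delta t =
0.04$ s (the reference problem size), a 30-s post-pulse cool-down
before lesion evaluation, and, for the treatment scenario, nineteen 4-s
pulses on a compact center-out spiral with 1.8 mm x 1.6 mm spacing and
22 s of cooling between pulses.

## Known limitations

* The linear beam stage substitutes for a nonlinear acoustic solver. With
  the published absorption ratio the linear stage concentrates more power
  at the focus than a shocked beam that loses energy to prefocal harmonic
  absorption, so simulated boiling onsets run earlier and bubble clouds
  larger than the reference values; the import path exists precisely so a
  nonlinear field can drive the same thermal pipeline.
* Straight-ray layer attenuation without refraction; acceptable for thin
  layers near normal incidence in the central cone, wrong for oblique
  geometries.
* No cavitation, no thermal lensing, no temperature-dependent acoustic or
  thermal properties (beyond $C_t(T)$ and perfusion shutdown), no
  inter-pulse residual-bubble enhancement — composite lesions from
  overlapping pulses are therefore underestimated.
* The equivalent model's concave-regime machinery ($W_+$, the cone) is
  tied to this transducer geometry and should not be generalized; for a
  plain spherical cap the convex branch suffices.
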