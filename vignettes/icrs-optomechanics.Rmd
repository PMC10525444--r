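---
title: "Corneal optomechanics of intracorneal ring segments: models and methods"
author: "icrsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corneal optomechanics of intracorneal ring segments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icrsim)
```

## The problem

Intracorneal ring segments (ICRS) are arc-shaped PMMA implants placed in a
stromal tunnel to flatten a keratoconic cornea. Whether a *progressive
asymmetric* segment (thickness and base width varying along the arc) corrects
the asymmetric aberration pattern of keratoconus better than a standard
symmetric segment is a design question that is naturally studied in silico:
simulate a generic healthy and a generic keratoconic cornea, implant six
candidate designs, and compare the induced curvature and aberration changes.

`icrsim` implements the *analysis side* of that study as a reusable, fully
synthetic pipeline: surface generation, a simplified membrane-mechanics
model, biconic and sagittal-curvature analysis, sixth-order Zernike
decomposition, and the refraction arithmetic that aggregates surface and
axial-length changes into an effective refractive change per scenario.

## Conventions

One sag convention is used throughout: `z` is the axial sag in mm, zero at
the pre-operative apex and increasing posteriorly. "Elevation" is `-z`
(anterior-positive), so the most elevated point of a surface is the sag
minimum, a keratoconic cone *subtracts* from the sag, and a receding
(flattening) surface has increasing sag. Geometry is in mm (thicknesses in
um where stated), stresses and pressures in Pa, 1 mmHg = 133.322 Pa, and
curvature maps are in diopters.

## Synthetic surfaces

The healthy cornea is a biconic surface,

$$ z(x, y) = \frac{x^2/R_x + y^2/R_y}
  {1 + \sqrt{1 - (1+Q_x)\,x^2/R_x^2 - (1+Q_y)\,y^2/R_y^2}}, $$

sampled on a regular grid clipped to a circular zone (default 9 mm diameter,
0.1 mm step). The default radii/asphericities are the pre-operative healthy
anterior (7.37, 7.62, -0.25, -0.10) and posterior (7.91, 7.97, 0.63, 0.37)
values of the reference study shipped in `reference_curvature_table()`.

**Keratoconic cone.** The analytic form of the cone is not specified by the
source model (only its weakened zones are), so the generator uses the
simplest smooth localized protrusion: a Gaussian bump in elevation,
amplitude `A` at center `c` with decay length `w`,
`dz = -(A/1000) exp(-d^2 / 2w^2)`. Defaults `c = (0, -1)` mm (inferior cone,
the common keratoconus presentation), `A = 80` um, `w = 1.5` mm were chosen
once so that the synthetic keratoconic cornea behaves like an advanced
(grade-4-like) cone: its sagittal Kmax reaches ~64 dpt, its biconic refit
steepens by several diopters (fitted anterior radii ~6.2/6.8 mm, close to
the reference keratoconic row 6.15/7.24), and its most elevated point moves
off-axis — which is what the curvature module's re-origin rule requires.
The two weakening zones (multipliers 0.30 and 0.70 of healthy stiffness,
radii 1.25 and 2.5 mm) reproduce the keratoconic material rows of the model
material table; because the source description of which zone is "central"
is ambiguous, the assignment is configurable in `cone_spec()`, with the
intuitive default (weakest core).

**ICRS effect.** Tunnel creation and contact mechanics are out of scope, so
the post-operative geometry is *emulated* with a parametric perturbation
whose structure matches the reported post-operative pattern: a locally
restricted flattening of the zone enclosed by the ring on the implanted
half, and a smaller opposite-sign steepening on the diametrically opposite
half. Concretely the sag gains `dz(r, phi) = a(phi) (1 - (r/b)^2)^2` inside
`b` = optical-zone radius + maximal base width (exactly zero outside, so
elevation beyond the support is conserved to machine precision), with
`a(phi) = gain * thickness(phi) * width(phi)` interpolated linearly along
the 160-degree arc (raised-cosine tapers at the ends), a negative lobe of
relative magnitude 0.15 on the opposite half, and the angular variation
smoothly suppressed near the axis (a perturbation with angle dependence at
`r = 0` would be discontinuous). The gain default (400 um per mm^2 of local
cross-section) was calibrated once so the healthy average-symmetric
scenario flattens by ~3.1 dpt in mean meridional power, the scale of the
reference comparison; it is an emulation knob, documented as such, and not
a mechanical prediction. What the emulation deliberately does *not*
reproduce: the exact magnitude split between anterior flattening and
axial-length change of the FEM solution, and any epithelial or stromal
remodelling (absent from the source model as well).

## Membrane mechanics

The mechanics module reproduces the load path of the source model — Yeoh
hyperelastic stroma, 550 um joint thickness, 15 mmHg posterior pressure,
regional weakening, inverse stress-free geometry — with a deliberately
simplified discretization: flat incompressible membrane triangles instead
of structural shells, and the two stromal layers merged into one membrane
with summed thickness and thickness-weighted constants (C1 = 34.45 kPa for
healthy stroma). Bending, contact, tunnel expansion and solid implant
insertion are out of scope.

Per triangle, with reference metric $A$ and current metric $a$, the
in-plane right Cauchy–Green tensor is $A^{-1} a$; plane-stress
incompressibility sets the thickness stretch
$\lambda_3^2 = \det A / \det a$, giving
$I_1 = \mathrm{tr}(A^{-1} a) + \det A/\det a$ and the Yeoh energy
$W = C_1 (I_1 - 3) + C_2 (I_1 - 3)^2 + C_3 (I_1 - 3)^3$. Because
incompressibility is enforced exactly through the thickness stretch, the
volumetric penalty parameter `d` of the material table never enters the
solution; it is carried for completeness (its printed value's units are
ambiguous in the source, which is immaterial here). The follower pressure
is conservative with fixed or symmetric boundaries and enters as
$-p V_{\mathrm{fan}}$.

The solver is a Newton iteration on the total potential with a sparse
finite-difference element tangent, a backtracking (Armijo) line search,
incremental load stepping, and Levenberg-style diagonal damping that
activates when near-wrinkling (compressive) states make the tangent
indefinite. Convergence requires the residual below
`1e-8 * p * mean element area`, floored at the attainable accuracy of the
finite-difference tangent; near the optimum, steps whose predicted energy
decrease is below the roundoff of the total potential are accepted
directly, since a line search cannot resolve them.

**Inverse stress-free geometry.** The unloaded configuration is found by the
classic deflation fixed point `X <- X + damping (target - inflate(X))`
(damping 0.5, tolerance 0.1 um, at most 100 iterations) with an Anderson(1)
secant acceleration: the plain iteration contracts at only ~0.96 per step
for the slowest modes, while the accelerated one converges in ~16
inflations. One structural caveat matters: a membrane is insensitive to
single-node normal perturbations of its *reference* (they are pulled flat
under tension), so the inverse problem is well posed only for targets the
membrane can actually attain. The self-consistency checks therefore use a
target constructed as the inflated image of a spherical cap, for which the
composition `inflate(find_stress_free(target))` is verified to reproduce
the target within 0.1 um.

Default problem sizes — spherical-cap meshes of 10–14 rings by 16–28
sectors (161–393 nodes) — were chosen as the coarsest discretizations at
which the quantitative checks are comfortably met (small-pressure membrane
stress within 0.5% of the Laplace value `pR/2t`); everything in the test
suite then runs in seconds on one core.

## Curvature analysis

`fit_biconic()` performs Levenberg–Marquardt least squares of the biconic
model over a 5 mm zone, initialized from a paraxial sphere fit with
`Q = 0`, plus an apex sag offset `z0`: deformed post-operative surfaces do
not pass through the pre-operative apex, and without the offset the fit
absorbs the piston term into wildly biased radii. On noiseless biconic
surfaces the fit recovers parameters to better than 1e-6 relative across
`R in [5.5, 9]`, `Q in [-2, 2]`.

`sagittal_map()` computes the clinical *axial* curvature: at each point the
axial radius is the distance along the surface normal to the reference
axis, `R_axial = r / sin(alpha)`, converted to diopters by the
refractive-index step of the surface side (`0.375/R` anterior, `-0.042/R`
posterior, `R` in metres). The reference axis passes through the geometric
apex for healthy corneas and through the most elevated point for
keratoconic ones (`re_origin = TRUE`); at the origin itself the
direction-independent meridional (paraxial) limit from a local quadric fit
is used. Maps are evaluated on the surface's native Cartesian grid with
central differences (one-sided at the zone edge) rather than on a
resampled polar grid: the pre-installed numerical stack offers no bicubic
2-D interpolator, and native-grid evaluation avoids injecting interpolation
error into the sign-sensitive difference maps. A tangential (meridional)
mode is available as an option. Difference maps subtract pointwise on the
shared grid and are exactly antisymmetric.

## Zernike aberrations

Elevation over a circular pupil (default 5 mm, matching the optical-zone
analyses; the source never states its Zernike pupil, so it is configurable
and recorded in every output) is decomposed by linear least squares onto
the 28 orthonormal (OSA/ANSI) Zernike polynomials of radial orders 0–6,
with coefficients in micrometres of elevation. The OSA single-index
convention is used throughout; indices 1–14 carry the clinical names
(vertical tilt ... vertical quadrafoil) used in the reporting tables.
Fifth- and sixth-order terms are computed but excluded from headline
summaries, as they are clinically mostly irrelevant. The published
low-/high-order summary rows are not plain sums of the printed per-index
changes and their formula is unstated, so `aberration_table()` provides
*configurable* summaries (signed sums or RMS over orders <= 2 and >= 3) and
does not target those printed values. A ridge fallback (with a warning) is
applied only if the design matrix conditioning degrades, which does not
occur on the default grids.

## Refraction arithmetic

- `radius_to_power()`: `(n1 - n0)/R`, with a *convex-anterior-positive*
  sign convention (the literal printed formula has the opposite sign, which
  would make every anterior power negative).
- `mean_meridional_power()`: the scalar power of a biconic surface is the
  arithmetic mean of its two meridional powers. This rule was chosen
  because it reproduces the healthy-block per-surface dioptric changes of
  the reference table from the printed radii to within rounding (+-0.03
  dpt); mean-radius and geometric-mean alternatives remain available.
- `myopic_shift()`: an axial shortening `dAL` at total ocular power `D`
  shifts refraction by `D^2 |dAL|` (dAL in metres) — the first-order
  longitudinal magnification — reproducing the reported 0.13 dpt for
  36–37 um at 60 dpt. The keratoconic eye uses `D = 64.7` (60 plus the
  reported +4.7 dpt steepening).
- `effective_change()`: anterior + posterior surface-power change minus the
  myopic shift, reported at 1 decimal; flattening is negative. This
  aggregation reproduces all the per-scenario effective changes of the
  reference study from its printed table inputs.

Two reference-table quirks are handled explicitly rather than silently:
the keratoconic-block anterior dioptric changes are *not* recomputable from
the printed radii (the zone/averaging rule behind them is unstated), so the
effective-change reproduction uses the printed per-surface changes as
inputs; and the pipeline on synthetic surfaces reports both the per-surface
changes and the axial-corrected effective change as separate columns, since
the reference table's caption is ambiguous about which its per-surface
column means.

## What passing tests do and do not show

The generator produces noiseless (optionally Gaussian-noised), perfectly
gridded, single-valued surfaces; real topography has missing sectors,
tear-film artefacts, and alignment error, none of which are emulated. The
membrane model preserves the material law and load path but not shell
bending or contact mechanics, so its absolute displacements overestimate a
shell's; only ordering and sign properties (weakening steepens and
displaces more; stiffening displaces less) are treated as meaningful. The
ICRS emulation is a geometric stand-in whose gain is a calibration knob.
Consequently the acceptance-grade numerical claims are of two kinds only:
(a) arithmetic reproductions of published quantities from published inputs,
and (b) internal consistency properties (round trips, closed forms,
orthonormality, Laplace limits, monotonicities) — not predictions of
post-operative outcomes.

## A short tour

```{r tour, eval = FALSE}
library(icrsim)

## published arithmetic
reference_effective_changes()

## synthetic pipeline over two designs
rep <- run_pipeline(pipeline_config(scenarios = c("asym", "sym")))
rep$summary_table
plot(rep$maps[["KC pre-op"]])

## mechanics demo: weakened cornea bulges and steepens
cap  <- cap_mesh_sphere(theta_max = pi / 3)
weak <- apply_weakening(cap, cone_spec())
inflate(weak, 15 * 133.322)$apex_axial_displacement
```
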