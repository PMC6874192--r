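---
title: "Patient and compensator scatter factors: models, phantoms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient and compensator scatter factors: models, phantoms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protoscatter)
```

## The quantities this package computes

Passive-scattering proton delivery calibrates machine output as dose per
monitor unit (DMU) in a homogeneous water phantom, usually without the
patient-specific range compensator in the beam. Two correction factors relate
that calibration to the dose actually delivered at the calculation point in
the patient:

* the **patient scatter factor**,
  $\mathrm{PSF} = d_{p/c} \,/\, d_{vp/c}$, the ratio of the dose at the
  calculation point in the patient to the dose at the *same water-equivalent
  depth* (WED) on the central axis of a homogeneous water phantom, both with
  the compensator in the beam;
* the **compensator scatter factor**,
  $\mathrm{CSF} = d_{vp/c} \,/\, d_{vp/nc}$, the ratio of the water-phantom
  dose with the compensator to that without it, at the same WED;
* their product $\mathrm{CPSF} = \mathrm{PSF} \times \mathrm{CSF}$, the
  combined correction to the DMU.

`compute_scatter_factors()` runs this verification workflow end to end: dose
in the patient grid, reconstruction of the water verification geometry at
matched WED (`build_verification_geometry()`), and the two water
calculations. The three dose calls share the beam, the beamlet lattice and
the SOBP weights, so the identities PSF = 1 for a water "patient" and CSF = 1
for a zero-thickness compensator hold to floating-point exactness — both are
asserted in the test suite.

## The dose engine

Commercial pencil-beam algorithms and Monte Carlo codes are out of reach for
a self-contained package, and are not needed: the scatter factors are ratios
of doses at matched water-equivalent depth, so the exact depth-dose shape
cancels to first order. The engine therefore uses deliberately simple,
fully-documented components:

* **Range-energy relation.** Bragg-Kleeman power law
  $R = \alpha E^{p}$ with $\alpha = 0.0022\ \mathrm{cm\,MeV}^{-p}$,
  $p = 1.77$ (`bragg_kleeman_range()`, exact inverse provided).
* **Pristine depth dose.** An analytic curve: a slowly rising entrance
  plateau $0.33 + 0.12 (z/R)^2$ plus a Gaussian peak of width
  $w = \max(4\sigma_s, 0.25\ \mathrm{cm})$ centred at $R - 0.25 w$, tapered
  to zero within three straggling widths $\sigma_s = 0.012 R^{0.935}$ beyond
  the range, and normalised to unit maximum. The peak maximum always lies in
  $[0.95R, R]$.
* **SOBP construction.** `sobp_weights()` places pristine peaks at pulled-back
  ranges $R, R - M/(n-1), \dots, R-M$ and solves a nonnegative least-squares
  problem (via `pracma::lsqnonneg`) for weights that flatten the summed curve
  on a 0.2 mm depth grid across the modulation interval. The default peak
  density, one peak per 1.5 mm of modulation, keeps plateau ripple near 1%;
  this matters because the compensator shifts every beamlet's depth sample,
  so plateau ripple propagates directly into CSF values of interest (~1%).
  With only 15 peaks over 5 cm the achieved ripple is ~3%, still within the
  posted 4% max/min bound.
* **WED ray tracing.** `wed_along_ray()` performs exact voxel-boundary
  (Siddon-style) traversal, summing geometric segment length times the
  relative stopping power of each voxel. It agrees with a 0.02 mm
  midpoint-rule oracle to about 0.1% over random heterogeneous slab phantoms
  (asserted at 0.5%).
* **Lateral spreading.** Each beamlet fans from a point source at
  $z = -\mathrm{SAD}$ (default 200 cm) and deposits a 2-D Gaussian at the
  calculation plane whose variance combines the in-air source sigma, a
  Highland angle for the compensator material drifted over the air gap plus
  depth, and a Highland angle for the cumulative patient path in radiation
  lengths drifted over $d/\sqrt{3}$ (the uniform-scatterer approximation).
  The Highland angle is
  $\theta_0 = (14.1/pv)\sqrt{x/X_0}\,[1 + \tfrac{1}{9}\log_{10}(x/X_0)]$
  with $pv = E(E+2m)/(E+m)$. Per-beamlet inverse square is included.

Not modelled, on purpose: Fermi-Eyges moment transport, nuclear interactions
and the low-dose halo, aperture edge scatter, energy spectrum evolution with
depth, and any absolute Gy/MU calibration — dose is in arbitrary engine units
and only ratios are meaningful. Consequences: the *directions* of all
heterogeneity effects are reproduced, but magnitudes are compressed. The CSF
spread over the generated compensator family is about 0.6%, against factors
reaching 4% above unity in clinical data; the PSF response to air is driven
mostly by the inverse-square mismatch between geometric and water-equivalent
depth, which is one of several mechanisms in reality.

## HU classification and the stopping-power calibration

Field composition uses five HU classes: air, thin tissue, soft tissue, bone,
dense bone. The printed class boundaries are mutually inconsistent at two
edges (the lower bound of one class overlaps the upper bound of its
neighbour by one integer HU); we resolve this with right-closed bins at
edges −650, −500, 125, 500 and 1245 HU, which honours every upper bound and
all reference assignments (−800 air, 0 soft tissue, 600 dense bone, 125/126
soft-tissue/bone, 500/501 bone/dense-bone). HU below −1000 clamps to air,
above 1245 to dense bone, so `classify_hu()` is total on [−1024, 3000].

The HU → (RSP, density, 1/X₀) conversion is a piecewise-linear calibration in
the Schneider spirit, shipped as *data* (`inst/extdata/default_calibration.csv`)
with seven knots from air (RSP 0.001) through water (exactly 1.0 at 0 HU) to
dense bone (1.60 at 1245 HU); scattering strength is density scaled by 1.7
for the bone classes. The knots are a design choice reproducing the
qualitative water/air/bone ordering, not a scanner calibration; users supply
their own table via `read_calibration()` (CLI flag `--calibration`). Which
stoichiometric variant a clinical system uses is scanner-specific, so the
package deliberately exposes the calibration rather than hard-coding one.

## Synthetic phantoms and what they do (not) emulate

All phantoms are generated in code (`make_water_box()`, `make_slab_phantom()`,
`make_lung_phantom()`, `make_pelvis_phantom()`), on 0-based voxel grids with
the half-voxel centre convention and the beam along +z. Test and acceptance
runs use 18 cm cubes at 3 mm spacing — small enough for seconds-scale
pipelines, large enough that divergence, Highland widths and SOBP coverage
all operate at realistic relative scales.

**Lung.** A soft-tissue body with air bands (HU −800) at seeded z positions,
spanning the beam's-eye-view (BEV) cylinder laterally. Keeping the
heterogeneity constant in x,y within the BEV has two consequences that the
package's invariants rely on: the achieved air fraction equals the request
voxel-exactly (the last band is trimmed from the axis outward), and every
field ray sees the same air path, so the designed compensator stays
consistent with the water verification geometry. With randomly placed
spherical pockets, ray-to-ray WED variance lets pocket-rich off-axis rays
overshoot the beam range in the verification phantom, which both inverts
parts of the PSF trend and biases CSF low — we observed exactly that and
chose bands. At fixed seed the band set is *nested* in the air fraction
(lower-fraction air voxels are a subset of higher-fraction ones), which makes
the PSF family monotone by construction of the physics, not by averaging.

**Pelvis.** A soft-tissue body with a paired left/right dense-bone block
(HU 700 core, one-voxel HU 300 shell) whose medial faces meet at the central
axis, upstream of the target; the core grows in a fixed voxel order with the
requested fraction (again nested, again voxel-exact). Blocks that never
crossed the axis could not move the PSF in this engine — the PSF mechanism
runs through the central-axis WED — so the "lateral blocks" meet at the
midline, as pubic bone does in a lateral pelvic field.

Neither phantom attempts anthropomorphic realism: no parenchymal density
gradients, no CT noise or beam-hardening artefacts, no respiratory motion,
no immobilisation-device air gaps (an optional air slab can be added with
`make_slab_phantom()`). Passing trend tests on these phantoms therefore shows
that the pipeline responds to controlled heterogeneity in the clinically
observed directions — it does not validate dose accuracy in real anatomy.

## Compensator design and the IQR irregularity metric

`design_compensator()` traces a diverging ray from the source through each
lateral cell to the deepest target voxel on that ray and sets
$t = \max\{0, (R - \mathrm{WED_{distal}})/\mathrm{RSP_{comp}}\}$ (PMMA,
RSP 1.16, X₀ 34.1 cm; both overridable). Rays that miss the target inherit
the maximum thickness of their filled neighbours, iteratively — no other
smearing or margins. A closure test feeds the map back through the ray
tracer: thickness × RSP + distal WED returns the prescribed range within one
voxel's water-equivalent thickness on every target ray.

The irregularity metric is the interquartile range of thickness within a
radius of the central axis. Two conventions needed fixing:

* **Quantiles** use linear interpolation of order statistics
  (`stats::quantile` type 7), the common scientific-software default; the
  2×2 example {1,2,3,4} cm gives IQR 1.5 cm under this convention.
* **The radius** is $3\,\theta_0 L$ — three projected Highland sigmas (99.7%
  containment) for the *median* compensator thickness (floored at 0.1 cm so
  open fields keep a finite radius), at the energy whose Bragg-Kleeman range
  equals the beam range, drifted over air gap plus depth. Whether the
  clinical definition used 1σ, 2σ or a percentile is not recoverable from the
  available description; 3σ is the conservative choice and the multiplier is
  an explicit argument.

`make_rugged_compensator()` generates the family used to study CSF versus
IQR: a thin axis with a quadratic peripheral build-up carrying seeded
azimuthal lobes. The irregularity is peripheral by design — in a
Gaussian-kernel engine, extra material *near* the axis scatters fluence out
(CSF down), while an irregular thick rim scatters fluence in (CSF up); the
latter is the mechanism behind the positive IQR association in clinical
compensators, whose central region conforms to the target while the rim
follows the most variable anatomy. We verified both signs numerically before
fixing the design.

## Scenario planning choices

`run_scenario()` composes phantom → beam fit → compensator → factors →
composition → IQR. The beam fit picks the range as the deepest distal target
WED plus 0.3 cm and a modulation wide enough that the calculation point (the
target centroid, the isocenter surrogate) sits mid-plateau in both the
with- and without-compensator calculations. The aperture radius defaults to
the target's lateral half-width plus 1.2 cm — a conforming aperture; a much
wider opening sends smeared-thickness rays onto the distal falloff in the
verification geometry and biases CSF low. When a compensator is *imposed*
rather than designed, the range and modulation are extended by its maximum
water-equivalent thickness, as a clinical range choice would be; sweep
families share a single extension so that all members use identical SOBP
weights. The local axial depth-dose gradient at the calculation point is
reported (`gradient_pct_per_mm`) because points in gradient regions make the
factors sensitive to millimetre shifts.

## Empirical models

`fit_line()` is ordinary least squares (through `stats::lm`) of a factor on a
single predictor — percent air, percent dense bone, or IQR in cm. The
package ships no literature coefficients: the published regression constants
are not recoverable from the available text, so fits are produced from this
pipeline's own runs and exchanged as JSON (`write_fit_json()`), with a slot
for user-entered coefficients. `predict()` refuses fields that declare both
appreciable air (>5%) and appreciable dense bone (>2%) unless overridden —
single-predictor guidance only holds when one heterogeneity type dominates —
and flags predictions beyond 1.5× the fitted predictor range as
extrapolations.

## Degenerate inputs and error taxonomy

Invalid geometry or parameters raise `protoscatter_invalid_input`; an
unusable plan (zero dose, no target coverage) raises
`protoscatter_degenerate_plan`; corrupted packaged tables raise
`protoscatter_fixture_error` (checksummed on load); too few samples for a
statistic raises `protoscatter_insufficient_data`. The command-line front end
maps these to exit codes 2, 3, 4 and 2 respectively. Ties in the isodose
threshold are inclusive (≥); a zero fraction selects the positive-dose
support; beam ranges below the distal target WED produce an all-zero
compensator with a warning rather than an error.

## Known limitations

* Factor magnitudes are engine-compressed (see above); only identities,
  closures and directions are asserted, at the tolerances stated in the
  tests.
* The verification phantom preserves the source position, air gap and
  compensator placement exactly; whether a clinical verification plan
  preserves the aperture-to-skin distance is an assumption we make and note.
* Composition uses the BEV cylinder by default; the 50% isodose region of a
  computed dose grid (`isodose_mask()` at inclusive threshold on the 3-D
  region) is available but slower, and which of the two a clinical histogram
  used is not determinable — both are exposed.
* The point-of-calculation sensitivity in gradient regions is reported, not
  corrected.
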