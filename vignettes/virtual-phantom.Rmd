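---
title: "A virtual cylindrical diode-array phantom for MR-linac QA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual cylindrical diode-array phantom for MR-linac QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcqa)
```

## The problem

Patient-specific QA on a 1.5 T MR-linac is commonly done with a cylindrical
diode-array phantom: 1386 diodes wound on a helix at 104 mm from the cylinder
axis, read out as an "unfolded" 2D chart and compared against the treatment
planning system's (TPS) calculated dose with distance-to-agreement (DTA) and
gamma-index statistics. For the TPS to calculate dose inside the phantom, the
phantom itself must be modelled. Vendors recommend a single bulk relative
electron density (RED) override; in a 1.5 T field, however, the electron
return effect makes the internal density layering of the device matter, and a
single bulk value that matches the exit/entrance dose ratio (EEDR) misplaces
dose elsewhere.

`arcqa` implements the alternative: a *virtual phantom* built from five
concentric density rings plus the setup-platform objects, written out as
standard DICOM objects that any TPS can ingest, together with the calibration
metric (EEDR), the analysis statistics (DTA, gamma), and the iterative RED
tuning loop. A deterministic ray-trace dose engine stands in for the TPS so
the whole workflow runs end to end in tests.

## Detector helix and chart conventions

The array is 21 helix turns of 66 diodes (22 circuit boards of 3), at exactly
360/66 degrees angular spacing, offset half a spacing so no diode lies on the
anterior or posterior pole. The axial coordinate advances 10 mm per
revolution; turns stack to span 210 mm centered on the isocenter plane.

The unfolded chart uses the vendor's nominal convention rather than the true
arc length: adjacent diodes are 10 mm apart in chart arc, so a turn spans
arc = -325 ... +325 mm (the true circumference 2*pi*104 = 653.5 mm differs by
3.45 mm per turn; the mismatch is absorbed at the posterior seam), and the
chart axial coordinate is the turn's nominal position (multiples of 10 mm)
even though the physical axial coordinate varies continuously within a turn.
This is the only reading under which the two entrance diodes of the central
turn can share the printed chart positions (-5, 0) and (5, 0).

Two geometry conventions are not fixed by published material and are exposed
as configuration in `detector_array_spec()`:

* the handedness of positive arc (default: positive arc toward +x), and
* the within-turn axial advance direction. The default (-1: physical z
  decreases as arc increases) is the direction for which the four
  seam-adjacent exit diodes land on the printed chart positions
  (325, 10), (325, 0), (-325, 0), (-325, -10) as the four diodes physically
  nearest the exit pole; the opposite handedness would put the off-center
  pair at (-325, 10) and (325, -10) instead.

Entrance/exit diode selection for the EEDR rotates with the beam: diodes are
ranked by angular distance to the beam entry (or exit) pole, ties broken by
physical axial distance from the isocenter plane; the two (entrance) or four
(exit) best are used.

## Phantom model

Five rings (outer radii 133.0 / 110.0 / 103.4 / 100.0 / 75.0 mm) named
Outer, Complex, Detectors, Inner, Insert carry REDs 1.130 / 1.200 / 1.000 /
1.130 / 1.130; the setup platform contributes six polygonal objects at RED
1.350. The published source does not print the platform outlines, so the
default in `platform_objects()` is a clearly labelled synthetic fixture
(three mirror-symmetric rectangles per side beneath the phantom); real
outlines can be supplied as polygons.

The pseudo-CT is 121 slices of 512 x 512 pixels at 0.97658 mm spacing and
2 mm slice thickness, all CT numbers zero: densities enter the TPS only
through structure overrides, never through CT numbers, so the identity
rescale is the right convention. Centering the in-plane grid on the axis
makes the first-pixel corner coordinate -(512-1)/2 x 0.97658 =
-249.51619 mm. The published Image Position Patient lists z = 0; we read
that as the central slice's tag and center the 121 slices on the isocenter
plane (z = -120 ... +120 mm), which is what "the isocenter coincides with
the phantom center" requires. The rings span the full slice stack (the
published description does not bound them to the 210 mm detector region;
this is configurable).

Voxelization assigns each voxel center the RED of the innermost containing
structure (last-overriding entry in the RED table); voxel centers exactly on
a ring boundary belong to the inner ring — the tie-break is documented
because TPS bulk overrides behave this way and it keeps results
grid-deterministic. There is no partial-volume weighting. Background is RED
0 (vacuum-like): only relative attenuation matters to the ray-trace engine,
and a zero background makes the inverse-square limit exact.

## DICOM mapping

One constant maps frames: the phantom's cylinder axis is DICOM z (slice
stacking), the anterior direction is DICOM -y (head-first supine), x is
shared; so phantom (x, y, z) is written as DICOM (x, -y, z). Files are
explicit-VR little-endian Part-10: a CT series (16-bit pixels, identity
rescale, shared frame-of-reference UID), an RT Structure Set (one ROI per
structure, closed planar contours referencing the slice positions), and
grid-type RT Dose (16-bit unsigned with `DoseGridScaling = max/65535`,
exact at the maximum and within half a quantum elsewhere). Round trips are
covered by tests, including a cross-check that `pydicom` reads the files
with identical geometry and pixel values.

## Dose sampling and normalization

Calculated dose grids are sampled at diode positions with trilinear
interpolation (dose grids are ~2 mm while the geometry is sub-mm;
nearest-neighbor would alias the helix against the grid). Plug-point doses
use the 0.25 cm radius sphere convention: the mean over a fixed,
deterministic quasi-uniform ball of 256 points built as a 128-point
Fibonacci spiral plus its point reflection — the central symmetry makes the
sphere mean *exactly* the center value on any linear field, and no RNG means
exact reproducibility.

Normalization modes mirror the published figures: by the mean of the two
entrance diodes, by the sampled axis dose, or by an explicit reference. The
calibration dose of the 10 x 10 cm, gantry-0, 200 MU beam is the mean of the
two entrance-side central-turn diode doses.

## EEDR, MU rescaling and RED tuning

The EEDR is the exit-side four-diode mean over the entrance-side two-diode
mean. Relative differences are `100 x (calc - meas) / meas`: the published
pair 0.3342 vs 0.3207 gives 4.2%. (The second published pair, 0.3229 vs
0.3207, prints as 1.0% but is 0.69% by direct arithmetic; the package
computes the arithmetic value and does not attempt to reconcile the printed
rounding.) `rescale_mu()` multiplies MU by measured/calculated mean dose,
which rescales engine doses exactly linearly.

`tune_red()` bisects the RED of one layer (default Complex, bounds
1.130-1.250; the platform uses 1.320-1.380) against a target EEDR.
Monotonicity is verified at the endpoints before bisection, and an
unreachable target reports the attainable interval. Termination is by EEDR
tolerance *or* a RED bracket below 0.001; the default tolerance is 1e-8,
deliberately tiny, because in a pure-attenuation engine the EEDR responds to
the Complex RED only through the ~1.2 mm difference between the exit and
entrance chord lengths through that shell — a loose dose tolerance would
accept REDs far from the generating value. With the deterministic engine the
response is exactly monotone, and tuning recovers a generating RED to within
the 0.001 bracket.

## DTA and gamma analysis

The reference is the measured-like point set at the diode chart positions;
the evaluated distribution is the calculated unfolded chart, bilinearly
interpolated (the plan dose is searched, as in the vendor software). The
search grid is step DTA/10 within radius 3 x DTA, which caps reportable
gamma near 3 — standard practice. Local mode normalizes the dose difference
by each reference point's own dose, global mode by one normalization dose
(default: the maximum reference dose). The low-dose threshold is applied to
reference doses relative to the *normalization* dose in both modes; vendor
threshold semantics are not published, so this choice is documented and
configurable through the `normalization` argument. DTA passes a point whose
own-position dose difference is within tolerance or whose reference dose is
crossed by the evaluated distribution within DTA (detected as a sign change
on the interpolated search disc). Both statistics are checked against
naive brute-force oracles on small grids, and the expected orderings hold:
pass rates are monotone under criteria loosening, and local never exceeds
global when reference doses do not exceed the normalization dose.

## The synthetic dose engine

The engine is deliberately simple and fully deterministic:

```
D(p) = MU x output x (SAD / r)^2 x B(d_eff(p)) x inside_field(p')
```

with `r` the source distance, `d_eff` the water-equivalent depth from
fixed-step midpoint ray marching through the RED volume (0.5 mm step;
outside the grid counts as background), `B` a linear buildup ramp from the
`entrance_factor` (0.5) at zero depth to 1 at `buildup_depth` (15 mm)
followed by exponential decay `exp(-mu_water x d)`, and a hard field
aperture projected from the isocenter plane. `lateral_shift` displaces only
the aperture test along the crossline direction — a one-scalar mimic of the
magnetic-field crossline dose shift, default off. It is explicitly *not* a
Monte Carlo or magnetic transport model: no scatter, no electron transport,
no angular detector response.

`mu_water = 0.00362`/mm is a calibration constant, not physics: it is the
closed-form value for which the default 5-layer phantom's calculated EEDR
for the 10 x 10 cm gantry-0 beam lands near the published measured 0.3207
(the water-equivalent exit-minus-entrance depth difference through the
layers is 234.2 mm, and `(1331/1539)^2 exp(-mu x 234.2) = 0.3207` gives
`mu = 0.00362`). The default `output` of 0.01 Gy/MU sets a convenient
absolute scale.

Numerical rules: the march step must not exceed half the smallest voxel
spacing (enforced with an error), so engine work uses coarse RED grids
(2 mm spacing via `engine_grid()`), while the 512-grid pseudo-CT serves
DICOM serialization and QA plumbing. RED lookups are nearest-voxel,
matching the piecewise-constant override semantics; ring-boundary placement
is therefore quantized to half a voxel, which bounds water-equivalent depth
errors on 1 mm grids to about 1 mm over a full traversal.

One geometric subtlety: because the sampling diodes sit 2.727 degrees off
the beam poles, the zero-density (inverse-square only) EEDR is 0.748202
from the true diode positions, not the pole-to-pole value
(1331/1539)^2 = 0.747961; the two agree only to ~2.4e-4. Tests assert the
exact off-axis value and treat the pole formula as an approximation.

## What the tests do and do not show

The synthetic generator reproduces the study *conditions* — geometry,
densities, beam protocol (gantry series every 2 degrees with the 8-18
degree exclusion, 174 beams; 25-point plug grid; 10 x 10 cm 200 MU
calibration beam) — but not clinical beam physics. Passing tests establish
that the geometry, serialization, metrics and tuning loop are correct and
self-consistent; they say nothing about agreement with a real MR-linac,
which requires the commercial TPS and a physical phantom. Published
clinical passing-rate tables are therefore out of scope by design.

Problem sizes used in the tests are the package's own choices: 2 mm RED
grids with short axial extents for engine properties, 1 mm grids for the
analytic-chord cross-check, and chart-sized (tens of points per side)
distributions for the gamma/DTA oracle comparisons.

## Known limitations

* No electron return effect, scatter, or detector angular dependence in the
  engine; `lateral_shift` is a crude aperture shift, not transport.
* Only physical diodes are modelled; no interpolated "virtual" diodes in
  the chart.
* The platform outlines are synthetic defaults; supply measured polygons
  for quantitative platform-attenuation work.
* DICOM support covers exactly the objects and tags this workflow needs
  (explicit-VR little-endian only); it is not a general DICOM library.
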