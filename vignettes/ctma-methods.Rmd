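---
title: "Measuring lower-leg deformity by contralateral mirroring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lower-leg deformity by contralateral mirroring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctma)
```

## The measurement problem

Rotational malalignment after intramedullary nailing of the tibia is
common (reported in up to a fifth of cases), and the established ways of
measuring it — clinical examination, plain radiographs, or manual
angle construction on CT slices — depend on an examiner choosing
reference landmarks by hand. `ctma` implements a fully computational
alternative built on one anatomical assumption: the two lower legs of
the same person are (nearly) mirror images. If the uninjured side is
mirrored and laid over the injured side so that the *proximal* segments
coincide, whatever rigid motion is still needed to bring the *distal*
segments into coincidence is exactly the deformity of the distal segment
relative to the proximal one.

The pipeline is:

1. extract bone surfaces from CT (Hounsfield thresholding seeded by a
   user click per bone);
2. mirror the contralateral (left) leg about a sagittal plane;
3. register the mirrored-left proximal segment onto the right proximal
   segment (rigid, iterative closest point) — this defines the common
   reference frame;
4. register the distal segments the same way; the residual rigid
   transform **is** the deformity;
5. report it as three centre-of-mass (COM) translations (mm) and three
   Euler rotations (degrees), plus two registration-quality gates.

## Coordinate frame and conventions

All geometry lives in a canonical patient frame: **X** left→right,
**Y** front→back, **Z** feet→head, units millimetres.  (Note this X runs
opposite to the DICOM LPS X; the NIfTI loader has a flip flag.)  The
clinical reading of the rotations is:

| axis | rotation reported as |
|------|----------------------|
| X (left–right) | recurvatum (+) / antecurvatum (−) |
| Y (front–back) | varus (+) / valgus (−) |
| Z (feet–head)  | internal (+) / external (−) rotation |

Angles are **clockwise-positive when looking along the positive axis**,
i.e. the negative of the mathematical right-hand convention; this is the
sign convention of the clinical motion-analysis software the package
emulates, and `euler_angles()` / `rotation_from_euler()` implement it
symmetrically.  The decomposition order is fixed-axis X, then Y, then Z
(`R = Rz·Ry·Rx`).  The order is not anatomically canonical, but at the
magnitudes seen in healthy-leg comparisons (≤ 2–3°) all six orderings
agree to better than 0.05°, which the test suite checks explicitly; the
fixed choice simply makes results reproducible.  At gimbal lock
(|rotY| = 90°) the X/Z split is resolved by `rotX := 0` and flagged.

The COM translation is reported as the displacement **of the distal
segment's centre of mass** under the residual transform, not as the raw
translation column of the transform. The raw column depends on where the
origin happens to be; the COM displacement is origin-independent. The
COM itself is the mean of an area-uniform cloud of points spread over
the surface (default 10,000 points, fixed seed 0), mimicking how the
clinical software derives it; `exact_surface_centroid()` provides the
closed-form value as a cross-check, and the sampled COM converges to it
as the cloud grows.

## Registration

`icp_register()` is a trimmed point-to-surface ICP:

* a cloud of `n_points` (default 100,000) is spread area-uniformly over
  the moving surface once, with a fixed seed;
* each iteration finds the **exact** closest point on the fixed triangle
  mesh for every cloud point (a uniform spatial grid in compiled code
  makes this fast), discards the worst `trim_fraction` (default 10 %)
  of correspondences, and solves the rigid update in closed form
  (SVD/Kabsch, determinant forced to +1 so a reflection can never be
  returned);
* iteration stops when the trimmed mean distance improves by less than
  `convergence_tol` (10⁻⁴ mm) or after `max_iterations` (100). The
  trimmed objective is provably non-increasing, which the tests assert
  per iteration.

Point-to-surface correspondences (rather than point-to-point between two
clouds) remove sampling-density bias; trimming gives the robustness to
localized artifacts that surface registration of large bone areas is
known for — the tests weld a bump of ~5 % surface area onto one mesh and
require the result to move by under 0.2°.

Fit quality is measured on `fit_points` (default 10,000) *freshly
sampled* points from a different RNG stream, so the reported quality is
not the quantity the optimizer minimized, and is gated at a mean
surface distance of 0.5 mm. Both gates (proximal and distal) are carried
in every report; a failed gate flags the report unreliable but still
returns values. With 0.2–0.3 mm surface noise on both sides the mean
distance lands around 0.15–0.22 mm and passes; at 1 mm noise it fails —
the gate separates usable from unusable registrations rather than
polishing numbers.

Initialisation: centroids plus principal axes, with the four-fold
proper-rotation sign ambiguity resolved by the candidate with the
smallest mean distance to the fixed surface, falling back to
centroid-only alignment for shapes with no distinct axes (a sphere).

## The two-stage pipeline and its pitfalls

`analyze_pair()` follows the static-proximal / moving-distal design, but
three implementation details matter and were chosen after the naive
version measurably failed:

* **Cut correspondence.** Segments are defined as fractions of the
  Z-extent (defaults 0.30 proximal / 0.30 distal — wide enough to
  include the tibial plateau, fibular head, plafond and malleoli, while
  excluding the featureless mid-shaft). Cutting each side by its *own*
  extent breaks down as soon as the two sides are posed differently, so
  the moving (mirrored) leg is coarsely aligned to the reference leg
  first and then cut at the *reference* planes.
* **Clip/register iteration.** Even then, the material caught by a fixed
  plane depends on the very deformity being estimated: a 10 mm axial
  shift moves 10 mm of bone across the cut. Each stage therefore
  iterates (≤ 3 passes) cut → register → re-cut at the reference plane
  mapped through the current estimate, starting each ICP from matched
  segment centroids. Without the centroid start, ICP creeps along the
  near-cylindrical diaphysis and stalls visibly short of the optimum.
* **Axis canonicalization.** If the reference leg arrives more than 15°
  off the Z axis, the whole problem is rotated so its principal axis is
  on Z before cutting (and legs within 15° are left untouched, so
  reported axes are the patient's). A leg lying sideways otherwise gets
  "proximal 30 % by Z" slices that are anatomically meaningless.

A guard aborts with an orientation error if the proximal registration
asks for more than a 90° rotation on top of the coarse alignment — the
signature of sides that were mixed up or already mirrored.

## Cohort statistics

For a cohort, each subject contributes one six-parameter row, and the
left/right symmetry question is answered per parameter: mean, median,
SD (n−1), SEM, and the 95 % confidence interval of the mean using the
Student t quantile with n−1 degrees of freedom (for n = 10,
t₀.₉₇₅ = 2.2622). A parameter whose CI excludes zero is flagged
asymmetric. Recomputing the published reference cohort's intervals from
its per-subject values reproduces every printed bound to ±0.001 under
the t quantile but not under a normal quantile, which confirms the
choice. Normality is tested per column with Shapiro–Wilk (Royston's
algorithm, via `stats::shapiro.test`) and the Lilliefors-corrected
Kolmogorov–Smirnov test (via `nortest::lillie.test`), with the
Lilliefors p reported as a "≥ 0.200" lower bound beyond the tabulated
range, matching mainstream statistical software output. One caveat is
packaged with the reference table: its published axial-rotation (ROTZ)
mean and median were evidently computed on unrounded data and differ
from recomputation on the rounded per-subject values by about 0.005
and 0.011 respectively; the loader's self-check therefore uses a 0.01
tolerance on column means.  The mention of RMSE in the source protocol
is read as describing these summary statistics; an explicit per-column
RMS-about-zero is available as `rms_about_zero()`.

## The synthetic phantom

Patient CT data cannot ship with a package, so validation rests on a
parametric phantom (`phantom_spec()` / `make_leg()` / `make_cohort()`):
a tibia modelled as a tapered, waisted tube with a *slightly elliptical
cross-section that twists ~20° along the shaft*, a flattened plateau
bulb, a plafond bulb and a medial malleolus; and a fibula as a slender
offset tube with head and lateral malleolus. This is deliberately
minimal anatomy: the pipeline consumes surface geometry, and what it
needs from that geometry is the absence of the symmetries that make
rigid motion unobservable — the twist makes torsion visible on the
diaphysis, the bulbs and bow break axial and mirror symmetries, and the
fibula's 36 mm lateral offset gives torsion a long lever arm.

The left leg is generated as the *exact* mirror of the right, after
which deformities are injected by rigidly transforming the distal
vertices (sharp cut, or blended over a 20 mm smoothstep band whose
fully-deformed region stays clear of the analysed segment). Ground
truth in the report's sign convention is derived in closed form by
conjugating the injected transform with the mirror, and
`make_cohort()` inverts that conjugation to construct injections that
realize *drawn* report-space deformities exactly — so recovery tests
compare like with like. Surface noise is added independently per side
along vertex normals, N(0, sd).

What the phantom does **not** emulate: real cortical-surface texture,
partial-volume and beam-hardening effects, contrast enhancement, joint
surfaces, or true anatomical left/right asymmetry. Passing the phantom
suite therefore demonstrates that the *algorithm* recovers known rigid
deformities through the full mirror–segment–register–decompose chain —
it does not certify accuracy on clinical CT.

`rasterize_meshes()` closes the loop for the segmentation module:
parity ray-casting voxelizes the (watertight) phantom bones at chosen
spacing into air/soft-tissue/bone Hounsfield levels, seeded region
growing (26-connected, nearest-seed tie-break in mm) segments them
back, and boundary-face extraction plus Taubin smoothing (λ = 0.5,
µ = −0.53, 10 passes — approximately volume-preserving, unlike plain
Laplacian smoothing) returns meshes whose registration against the
source phantom agrees to ~0.01° and ~0.03 mm at 1.25 mm voxels. The
unsmoothed boundary surface has signed volume exactly equal to voxel
count × voxel volume, which anchors the volume tests. The region-growing
segmenter is this package's own stand-in for the proprietary
click-plus-threshold segmentation of clinical workstations and is
labelled as such in its documentation.

## Numerical choices and problem sizes

* Rigid-transform validity is enforced at 1e-9 (orthonormality,
  det = +1); Euler round-trips are exact to 1e-9 away from gimbal lock.
* STL is read/written in both binary and ASCII; 32-bit storage bounds
  round-trip error at ~1e-5 mm relative. Exactly coincident vertices
  are welded on read.
* Degenerate inputs error loudly: empty meshes, zero-area surfaces,
  seeds below the HU threshold, constant columns in normality tests,
  sub-minimal sample sizes.
* Test and validation runs use reduced problem sizes chosen to keep the
  full suite within a few minutes on one core: phantom resolution 0.5
  (≈ 3,800 faces per leg; 0.75 for noise studies, where the coarser
  mesh's larger noise bumps would otherwise dominate the error budget)
  and 3,000/2,000 registration/fit points. Defaults for real use remain
  100,000/10,000 points as in the emulated clinical protocol. With
  these sizes a single `analyze_pair()` runs in a few seconds; accuracy
  at full size is strictly better because every error source shrinks
  with more points.

## Known limitations

* Rotations are reported in the proximally-aligned reference frame;
  if the reference leg is tilted by more than 15° the axes are those of
  the canonicalized (principal-axis) frame, not the scanner's.
* The feet-to-head sense of a nearly-horizontal leg is taken from the
  input orientation; the package cannot recognise an upside-down leg
  anatomically.
* DICOM series are not read directly (no DICOM reader is available to
  this package); convert to NIfTI first.
* The method compares a leg with its mirrored contralateral side, so it
  measures *relative* deformity and inherits any true anatomical
  left/right asymmetry of the subject — in the published reference
  cohort that asymmetry is visible as a varus-direction offset (the
  ROTY CI excludes zero) while all other parameters are symmetric.
* Intra-operative use is out of scope, as is non-rigid or scaled
  registration and fracture-fragment (rather than whole-segment)
  analysis.
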