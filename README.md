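# ctma — lower-leg deformity from mirrored-contralateral CT registration

Rotational malalignment of the tibia after intramedullary nailing is
common, and the usual ways of measuring it (goniometry, plain films,
manual angle construction on CT slices) depend on hand-picked landmarks.
`ctma` implements a fully computational alternative for R: mirror the CT
surface of the uninjured contralateral leg, rigidly register the
**proximal** bone segments as a stationary reference, rigidly register
the **distal** segments as the moving object, and read the deformity off
the residual rigid transform.

For a residual transform `T = (R, t)` acting in the proximally-aligned
patient frame (X left→right, Y front→back, Z feet→head, mm), the report
is the six-parameter vector

```
COM  = T(c) − c                 (c = distal-segment centre of mass)
rot  = (rotX, rotY, rotZ),  R = Rz(−rotZ)·Ry(−rotY)·Rx(−rotX)   [degrees]
```

with angles clockwise-positive looking along each positive axis, so that
rotX reads as recurvatum/antecurvatum, rotY as varus/valgus and rotZ as
internal/external rotation. Registration is trimmed point-to-surface
ICP (default 100,000 surface points, 10 % trim) with fit quality
measured on 10,000 independently sampled points and gated at a mean
surface distance of 0.5 mm.

The package covers the full workflow: STL I/O and mesh primitives,
Hounsfield-threshold seeded bone segmentation with surface extraction,
registration, the mirroring pipeline, cohort symmetry statistics
(t-based 95 % CIs, Shapiro–Wilk and Lilliefors tests), a parametric
leg-pair phantom generator with injectable ground-truth deformities, and
the packaged per-subject reference cohort of 10 healthy adults.

## Worked example

Generate a synthetic leg pair whose left distal segment carries a known
10° torsion, analyze it, and tabulate the reference cohort:

```r
library(ctma)

spec <- phantom_spec(resolution = 0.5, deformities = list(
  list(segment = "distal", axis = "z", angle_deg = 10, transition = "sharp")))
ph <- make_pair(spec, subject = "demo")
report <- analyze_pair(ph$pair,
                       params = reg_params(n_points = 5000, fit_points = 3000))
print(report)
#> ctma_report [demo]
#>   COM translation (mm):  X  +0.006  Y  -0.679  Z  +0.000
#>   Rotation (deg):        X  -0.000  Y  -0.000  Z  -9.996
#>   (X: antecurvatum, Y: valgus, Z: external rotation)
#>   fit: proximal 0.000 mm, distal 0.000 mm (gate 0.50 mm)
```

The injected right-handed +10° torsion of the left leg appears, after
mirroring, as −10.0° (external rotation) with both fit gates passed;
`ph$truth` carries the exact expected six-vector for comparison. The
small COMY value is real, not error: the torsion is applied about the
segment centroid, which displaces the centre of mass of the slightly
asymmetric distal segment.

```r
ref <- load_reference_cohort()
print(cohort_report(ref[, -1]))
#> Cohort symmetry summary:
#>  parameter  n   mean median    sd   sem ci_low ci_high crosses_zero   rms
#>    COMX_mm 10 -1.626 -1.092 1.864 0.589 -2.959  -0.292        FALSE 2.402
#>    COMY_mm 10 -0.739 -0.048 3.125 0.988 -2.974   1.497         TRUE 3.055
#>    COMZ_mm 10  0.910  0.867 3.255 1.029 -1.418   3.239         TRUE 3.219
#>   ROTX_deg 10 -0.264 -0.350 0.928 0.293 -0.928   0.400         TRUE 0.919
#>   ROTY_deg 10  0.703  0.717 0.465 0.147  0.370   1.035        FALSE 0.830
#>   ROTZ_deg 10 -1.189 -0.637 3.158 0.999 -3.448   1.071         TRUE 3.223
#> CI excludes zero (asymmetry): COMX_mm, ROTY_deg
#>
#> Tests of normality:
#>  parameter shapiro_W shapiro_p  ks_D  ks_p ks_p_display
#>    COMX_mm     0.922     0.371 0.211 0.200      >=0.200
#>    COMY_mm     0.956     0.738 0.184 0.200      >=0.200
#>    COMZ_mm     0.854     0.065 0.275 0.031        0.031
#>   ROTX_deg     0.954     0.721 0.132 0.200      >=0.200
#>   ROTY_deg     0.978     0.950 0.162 0.200      >=0.200
#>   ROTZ_deg     0.970     0.891 0.158 0.200      >=0.200
```

Healthy lower legs are symmetric on four of the six parameters; the
lateral COM shift (COMX) and the varus/valgus rotation (ROTY, CI
0.370–1.035°) exclude zero — the right legs of the reference cohort sit
slightly in varus relative to the left.

A thin command-line wrapper over the same functions ships at
`inst/cli/ctma.R` with subcommands `phantom`, `segment`, `register`,
`analyze`, `stats` and `run-full` (manifest CSV in, cohort CSV plus
summary/normality tables out).

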