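---
title: "Helical flow and wall shear descriptors: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical flow and wall shear descriptors: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroflow)
library(dplyr)
```

`coroflow` post-processes one cardiac cycle of coronary CFD output into
helical-flow, wall-shear and geometric descriptors, and runs the
segment-level statistics that compare non-stenosed and stenosed vessels.
This vignette explains the models behind each stage, the parameters that
matter, the numerical choices that were genuinely open, and what the
phantom-based validation does and does not demonstrate.

## Helical flow descriptors

Helical flow combines downstream translation with rotation about the flow
axis. Its pointwise measure is the helicity density `v . w`, the inner
product of velocity and vorticity. The four bulk descriptors are time-and-
volume averages over one cycle of period `T` and a volume of interest `V`:
`h1` averages the signed density (net handedness), `h2` averages its
magnitude (how much helical motion exists regardless of direction), and
`h3 = h1/h2`, `h4 = |h1|/h2` quantify the balance of counter-rotating
structures (`h4 = 1`: single-handed; `0`: perfectly balanced). The local
normalized helicity `LNH = v . w / (|v||w|)` is the cosine of the angle
between the two vectors and is used for visualisation; where
`|v||w| < 1e-12` (SI) the value is defined as 0 to avoid 0/0 at stagnation
points. The floor is configurable (`epsilon` in `lnh_field()`).

Two integral conventions were open:

* **Normalisation of `h1`/`h2`.** The `1/(T V)` prefactor follows the
  helical-flow descriptor literature, so `h1` and `h2` carry units of
  m/s^2 and are comparable across vessels of different volume.
* **Cycle-averaged LNH.** The package averages the instantaneous LNH over
  the snapshot times with trapezoidal weights — identical to the arithmetic
  mean for uniform sampling, and well defined for non-uniform snapshot
  spacing.

### Vorticity reconstruction

Solver exports rarely contain vorticity, so it is reconstructed from cell
velocities. Each cell fits a local polynomial model of the velocity (linear
plus Hessian terms) to its neighbour stencil by least squares; the curl is
taken from the fitted gradient. The quadratic model makes the gradient
exact not only for affine fields (rigid rotation, uniform translation) but
for any velocity that is locally a degree-2 polynomial — which includes
parabolic (Poiseuille-type) profiles, the dominant near-wall structure in
tube-like vessels. First-order fits were measured to leave a few-percent
bias in `h1` on curved lattices at realistic resolutions, which motivated
the quadratic choice. Cells whose stencil cannot support the fit fall back
to a ridge-regularised solve and are counted in a warning.

The stencil is face-adjacency plus lattice diagonals; at one-sided
boundaries (wall, tube ends) second-layer partners are added so the
quadratic fit stays well-posed. For meshes read from files,
`cell_neighbors_from_cells()` derives the pairs from shared faces.

### Segment attribution

Volume cells and wall elements are attributed to anatomical segments (LAD,
LCx, diagonal, marginal) or to pre-/stenosed/post-stenosis regions by the
label of the nearest centerline point (`assign_segments()`), a tube map.
This is the natural choice when per-segment clipped meshes are not
available; it can misattribute cells near bifurcation carinae by up to the
local vessel radius.

## Wall shear descriptors

`TAESS`, `OSI` and `RRT` are computed per surface element from the wall
shear vector series, with trapezoidal time integration over the snapshots
of one cycle. Conventions chosen where definitions leave room:

* A single snapshot is treated as a steady solution: TAESS is the
  instantaneous magnitude and OSI is 0, with a `"steady"` status flag.
* An identically zero shear history would make OSI 0/0; it is defined as 0
  and flagged `"zero_shear"`.
* `RRT = 1/((1 - 2 OSI) TAESS)` is `Inf` at the `OSI = 0.5` or `TAESS = 0`
  pole; infinite RRT counts as exceeding any finite threshold in the
  exposure fractions.
* The adverse thresholds default to the literature values — TAESS below
  0.5 Pa and above 4.71 Pa, OSI above 0.1, RRT above 4.17 Pa^-1 — and the
  comparisons are **strict** inequalities, matching their "less
  than"/"greater than" definitions. Elements exactly at a threshold fall
  into the in-between band, and the three TAESS bands partition each
  segment's area exactly.
* Exposure percentages are normalised per labelled segment area.

When exports carry no solver-computed wall shear, `wss_from_velocity()`
derives it by projecting the adjacent interior cell's velocity onto the
wall tangent plane and differencing one-sidedly against the no-slip wall;
the apparent viscosity is evaluated at the resulting shear rate. This is
exact for linear shear with constant viscosity and first-order accurate
otherwise; exported WSS vectors are preferred when available.

## Centerline geometry

Average absolute curvature (tortuosity) and unsigned torsion are arc-
length-normalised integrals of the Frenet expressions in `c'`, `c''`,
`c'''`. Numerically the curve is resampled to uniform arc-length spacing by
natural cubic spline interpolation of each coordinate, and derivatives are
taken by central finite differences (5-point for `c'''`); the integrand is
evaluated on the interior support and normalised by its length. Smoothing
(`smooth.spline`) is available through the `smooth` argument but **off by
default**: VMTK-style centerlines and the phantoms are noise-free, and any
default smoothing would bias the curvature of strongly curved vessels.
The torsion integrand masks points where `|c' x c''|` vanishes (undefined
Frenet frame); an everywhere-straight curve returns 0 with a warning.

Stenosis delineation finds the global minimum-diameter point and computes
the degree against a reference diameter. Because "vessel diameter" could
mean the local minimum or a healthy reference, the package uses the branch
mean diameter excluding a guard window of ±3 minimum-diameters around the
minimum — a healthy-reference estimate that is robust to the lesion's own
narrowing — and spans the region two reference diameters up- and
downstream, clamped to the branch. The detection threshold defaults to a
degree of 0.2. Distal trimming (`trim_small_branches()`) truncates
branches at the first crossing below 2 mm diameter, mirroring the
resolution limit of CT-derived trees.

## Boundary conditions and rheology

Inflow uses the allometric law `Q = 1.43 d^2.55` with `d` in mm and `Q` in
mL/min — the unit convention of the scaling-law literature, exposed
explicitly since the law is not dimensionally homogeneous
(`ml_min_to_m3_s()` converts). At each bifurcation the flow split
`Q_sb/Q_mb = (d_sb/d_mb)^2.27` is combined with mass conservation
`Q_parent = Q_main + Q_side` (assumed; incompressible flow in rigid
vessels) and applied recursively, so outlet flows sum to the inlet flow to
machine precision. The "mean diameter" entering the split uses the
proximal third of each daughter branch (configurable), since daughter
vessels taper.

The generic coronary waveform is a two-lobed raised-cosine with diastolic
dominance: the diastolic fraction of the period (default 0.6) carries 70%
of the cycle volume by default, both configurable. It is a stand-in with
the right gross features (diastolic-dominant left coronary inflow), not a
patient waveform. All shapes are normalised analytically so the cycle mean
is exact to round-off.

Blood viscosity follows the Carreau–Yasuda model with the standard
literature constants (`mu_0 = 0.056` Pa s, `mu_inf = 0.00345` Pa s,
`lambda = 1.902` s, `n = 0.22`, `a = 1.25`, density 1050 kg/m^3), all
configurable and printed by the parameter object. Reynolds checks default
to the infinite-shear viscosity, the conservative (largest-Re) choice for
a shear-thinning fluid, against the laminar threshold of 2000.

## Statistics

The workflow mirrors standard practice in cohort haemodynamics studies:
Shapiro–Wilk normality at alpha = 0.05 gates every summary and test —
mean ± s.d. and Welch's t-test when normal, median [IQR] (type-7
interpolated quartiles) and the Mann–Whitney U-test otherwise. The gate is
applied **per group**, requiring both groups normal for Welch. Mann–Whitney
uses exact enumeration when both groups have n ≤ 12 and no ties, and the
tie-corrected normal approximation otherwise; `compare_groups()` also
accepts `test = "welch"`/`"mann_whitney"` to bypass the gate, which is
useful because small regular samples (e.g. consecutive integers) pass
Shapiro–Wilk and would otherwise route to Welch. Spearman correlations use
exact permutation p-values up to n = 9 without ties. Holm's step-down
adjustment is applied within each declared family — by default one family
for the group-comparison panel and one per correlation heatmap, mirroring
how such results are presented — with adjusted p < 0.05 called
significant. Degenerate inputs (constant samples) yield p = 1 with a flag
rather than an error, so automated study sweeps do not abort.

## The synthetic phantoms: what they do and do not show

The swirling-pipe phantom superposes axial Poiseuille flow with solid-body
swirl. Its helicity density is uniform (`v . w = 2 U Omega` with `U` the
centreline speed), its wall shear is purely axial with magnitude
`4 mu Q / (pi R^3)` (solid-body swirl exerts no wall shear), and counter-
rotating layouts give `h3 = 2 phi - 1` for a dominant volume fraction
`phi` (snapped to an angular sector boundary so the achieved fraction is
exact). Pulsatility is **quasi-steady**: the whole velocity field scales
with `Q(t)/Q_mean`, so time-averaging operators are exercised while the
ground truth stays closed-form (`h1` scales with the cycle mean of
`(Q/Q_mean)^2`). No Womersley or unsteady solution is attempted; phase lag
and near-wall unsteady structure of real coronary flow are therefore not
emulated. The mesh is a structured cylindrical lattice exposed through an
unstructured interface (points, connectivity, neighbour pairs), so the
integration code paths match what file-based CFD exports exercise.

The reversal wall-shear phantom emits the jump time twice (a zero-width
panel), so trapezoidal integration reproduces `OSI = f` exactly rather
than to first order. The copula group sampler draws descriptor pairs from
a bivariate normal with Pearson parameter `2 sin(pi rho / 6)`, making the
population Spearman correlation exactly the requested `rho`; group shifts
are expressed in s.d. units.

Passing the phantom oracles demonstrates correct implementation of the
descriptor definitions, integration operators and statistics — it does not
validate CFD accuracy, mesh quality on anatomical geometries, or the
physiological fidelity of the boundary-condition constants.

## Problem sizes and tolerances

The validation suite runs the helicity oracle at ~40k cells (recovering
`h1 = h2 = 4` m/s^2 to machine precision, comfortably within its 2% band),
geometry oracles at 200–500 centerline points (0.5–1%), the statistics
simulations at 200 replicates (family-wise error of Holm on null tables),
rank-correlation recovery at n = 2000 (±0.05), and the end-to-end study on
39 phantom cases at ~300 cells each. These sizes were chosen so the whole
suite gives tight oracles at interactive runtimes; all generators accept
larger `mesh_density`/`n_points` for convergence studies (curvature and
torsion converge at order ≥ 1 on helix refinement, and the vorticity
reconstruction is exact for quadratic fields at any resolution).

## Known limitations

* One cycle of snapshots is the input contract; transient start-up
  handling (discarding early cycles) is upstream of this package.
* Anatomical labels are input metadata; no automatic anatomy
  classification or centerline extraction from surfaces/images.
* The tube-map segment attribution is nearest-point, not a true clip.
* No turbulence, fluid–structure interaction, Womersley profiles,
  vortex-core extraction, or lumped-parameter outflow coupling.
* VTK I/O covers ASCII XML unstructured-grid and poly-data with inline
  arrays — the subset the package writes — not the full VTK zoo
  (appended/binary encodings, multiblock).
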