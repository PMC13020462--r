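---
title: "Modelling tetrapolar thoracic bioimpedance for pulmonary fluid monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tetrapolar thoracic bioimpedance for pulmonary fluid monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thoraximp)
```

## The problem

Pulmonary edema is the abnormal accumulation of extravascular lung water;
clinically relevant accumulations are on the order of 0.3--1.0 L above
baseline and pool in the lower lobes under gravity.  Because fluid is far
more conductive (sigma about 1.5 S/m) than inflated lung parenchyma
(about 0.09 S/m at 10 kHz), a four-electrode (tetrapolar) transfer
impedance measured on the chest surface drops as fluid accumulates.
`thoraximp` is a forward-modelling laboratory for this measurement: it
answers how large the impedance change is, where the measurement is
sensitive, and how the signal depends on electrode position, fluid
volume and excitation frequency.

## Model and governing equations

At the frequencies of interest (5--1000 kHz) the problem is quasi-static:
the potential obeys the conduction equation `div(kappa grad V) = 0` in the
thorax, where the admittivity is `kappa = sigma` in real mode or
`kappa = sigma + i * 2 pi f * eps0 * eps_r` when displacement current is
included.  The outer thorax surface and the airway walls are insulating
(`J . n = 0`).  Electrodes are modelled as zero-contact-impedance
equipotential surface patches (complete electrode model): the drive patch
carries a prescribed total current `I0` (1 mA by default), the return
patch is grounded, and sense patches float with zero net current.  This
matches the usual argument that metal electrodes are many orders of
magnitude more conductive than tissue, so their interior need not be
meshed.

The transfer impedance is computed two ways.  The *voltage* route reads
the floating sense-patch potentials of the drive solve,
`Z = (V_C - V_D) / I0`.  The *reciprocity* route solves the second lead
field (drive through the sense pair) and integrates the volume impedance
density

```
z = (1 / kappa) * (J_AB . J_CD) / I0^2      [Ohm / m^3]
Z = sum over elements of z * volume
```

with a non-conjugated dot product; in complex mode the reported scalar is
`|Z|`.  For first-order elements on the same mesh the two routes agree to
solver precision (the integral is the weak-form bilinear pairing of the
two solutions), which the test suite exploits as an internal identity,
together with reciprocity, regional additivity (contributions over any
partition of regions sum exactly to `Z`), current conservation, and the
exact conductivity scaling law (`kappa -> alpha kappa` divides `Z` by
`alpha`).

## Synthetic anatomy

The CT-segmented anatomy of a specific subject is not reproducible, so
the geometry module builds a parametric stand-in whose *volumes* are
pinned to the printed totals and everything else is simple and explicit:

* **Torso**: vertical elliptic cylinder (default semi-axes 0.149 x
  0.100 m, height 0.50 m), rescaled so that the analytic volume
  `pi a b h` equals the 23.4 L target exactly.  Flat caps are used: the
  caps are far from the electrodes and insulating either way, and flat
  caps make the torso volume a closed-form invariant.
* **Lungs**: per side, a vertically truncated half-ellipsoid -- the
  upper half of an ellipsoid, so the flat base (the lower lung margin,
  resting on the diaphragm and anchoring the electrode reference
  position) is the widest section and the apex tapers upwards, as in
  real lungs -- with the dilated heart subtracted to form the cardiac
  notch.  The horizontal semi-axes are auto-scaled (by 1-D root finding
  on a deterministic grid quadrature) until the total lung solid volume
  matches the 4.84 L target; the heart subtraction therefore makes the
  left lung about 17 % smaller than the right, as in real anatomy.
* **Heart**: an ellipsoid centred 2.2 cm left of the midline, slightly
  anterior, spanning roughly two thirds of its width into the left
  hemithorax (0.67 L).
* **Ribs**: 12 pairs of 5 mm-radius bars following a scaled copy of the
  torso ellipse, with sternal and spinal gaps; toggleable to isolate
  their effect.
* **Airways**: a trachea plus two main bronchi whose lumen is removed
  from the conductive domain; the exposed triangles become the insulating
  airway wall.
* **Fluid**: the intersection of a lung with the half-space below a
  horizontal cut plane (gravity pooling).  The cut height is found by
  bisection on the volume-below-height curve (piecewise-linear from the
  quadrature grid), reaching the target volume to well within 1 %.
* **Electrodes**: four 1 cm discs at the corners of an 8 cm square in the
  unrolled surface metric (arc length x height), centred laterally above
  the chosen lung.  At zero vertical offset the bottom pair is level with
  the lower lung margin.  Current is driven through the left vertical
  edge (A bottom, B top) and sensed across the right edge (C bottom, D
  top); the assignment is configurable because the reference description
  of the corner roles is not unambiguous.

Coordinates: z vertical (toward the head), anterior chest faces +y,
patient's left is +x, all SI units.

## Meshing and discretisation

No general-purpose mesh generator is available in this stack, and the
geometry is deliberately parametric, so the mesher is structured: a
graded elliptic-cylindrical lattice (radial fraction, cross-section arc
length, height) split into tetrahedra by the Freudenthal 6-tet
subdivision, with a conforming 3-tet wedge ring on the axis.  Identical
index-space splitting in every cell makes face diagonals agree between
neighbours, so the mesh conforms; the construction contains no
randomness, so meshing (and hence every sweep) is bitwise reproducible.

Resolution is spent where it matters: about 2 mm surface bands around
the electrode discs (the 1 cm patches are resolved to a few percent in
area), a radially graded boundary layer under the surface, and a
volumetric interior budget of 14 mm at the `normal` level.  The four
refinement levels scale the volumetric budget by 2.2 : 1.5 : 1.0 : 0.7
(about a three-fold element-size span); the nested electrode bands
(2 / 3.5 / 5.5 mm out to about 2.5 cm from each electrode row and
column) and the near-surface radial stack are held fixed across levels,
so the convergence study measures far-field volumetric discretisation
error rather than re-pixelisation of the electrode neighbourhood.
Typical element counts are about 210 k (coarser) to 680 k (fine)
tetrahedra.

Elements are labeled by classifying their centroids against the solid
model.  Pure centroid labeling leaves an O(h) staircase error at organ
interfaces that re-randomises at every refinement level; the package
therefore also classifies the four interior quadrature points of every
element and assembles with the *mean* admittivity of the sampled tissues
(partial-volume material averaging).  Interface elements thus carry
mixed admittivity, the interface error becomes smooth and small, and the
four-level convergence study lands inside the reference bounds (maximum
deviation from the finest level below 0.5 %, normal-vs-fine below
0.1 %).  Volumes and regional contributions keep the crisp centroid
labels, so region volumes always partition the mesh volume exactly.

During a fluid-volume sweep the mesh is generated once and only
relabeled per volume, so that impedance differences between volumes are
not confounded by remeshing; a 3.5 mm vertical refinement band spanning
the height range the air/fluid front traverses resolves the moving
interface consistently for every volume.

## Solver

First-order tetrahedral elements; assembly is fully vectorised and the
patch constraints are applied by condensing each electrode patch to a
single unknown.  One interior node is eliminated as the potential gauge
(the injection right-hand side is consistent), which makes the reduced
operator independent of which patches drive: a single sparse Cholesky
factorisation (CHOLMOD via `Matrix`) serves both lead-field solves and is
cached on the system object.  The solution is re-grounded to the sink
patch afterwards.  A Jacobi-preconditioned conjugate-gradient solver is
available (`solver = "iterative"`, default tolerance 1e-8 -- deliberately
far tighter than the 0.5 % acceptance checks, so solver error never
masquerades as model signal).  Complex solves use a fixed-point
iteration preconditioned by the real-part factorisation; it converges
because `omega eps0 eps_r / sigma` stays below about 0.6 for every
tissue and frequency in the shipped table, and it stops at a 1e-10
relative residual.

## Tissue properties

The six model tissues (inflated lung, soft tissue, rib bone, heart, body
fluid, stainless-steel electrode) carry sigma and eps_r over 5, 10, 50,
100, 200, 500 and 1000 kHz.  The 10 kHz column holds the exact values
used by the single-frequency experiments (e.g. lung 0.0932 S/m / 17 174;
fluid 1.5 S/m / 98).  The other columns are representative values
following Gabriel-type beta-dispersion trends (sigma non-decreasing,
eps_r non-increasing with frequency) and are marked as such in their
provenance column; users can substitute their own table from a TSV file.
Off-grid frequencies are interpolated log-log; extrapolation outside
5--1000 kHz is refused.  Real mode (`kappa = sigma`) is the default for
single-frequency work; complex mode is the default for frequency sweeps.

## The experiments

* `vertical_sweep()` moves the array upward from the reference position
  in 2 cm steps (default 0--10 cm; the maximum offset is a package
  default, as the reference protocol does not state one), re-meshing per
  position.
* `fluid_volume_sweep()` fills the lower lobe with 0--670 mL in six
  equispaced volumes (so the reference 0.670 L case is the endpoint) and
  fits Z against volume by OLS, reporting the slope in mOhm per 100 mL.
* `frequency_sweep()` evaluates `|Z|` at the seven tabulated frequencies
  under baseline and fluid conditions in complex mode.
* `mesh_convergence_study()` recomputes Z at the right lower position on
  the four refinement levels and reports deviations from the finest.
* `percent_delta_Z()` uses the no-fluid baseline as the denominator
  (the convention that makes the reported percent changes consistent
  with the vertical-profile figures), and `detectability_band()` flags
  points whose fluid-induced change exceeds a +/- 2 % band around the
  baseline.

## What the synthetic generator does and does not emulate

The generator reproduces the gross properties the reference anatomy is
known by: total volume, lung volume, bottom-heavy lungs that taper
toward the apex (so the healthy impedance falls as the array moves up),
left/right asymmetry from a heart left of midline, ribs, insulated
airways, lower-lobe fluid pooling, and the electrode protocol.  The
baseline transfer impedance at the right lower position comes out near
14.5 Ohm against the 15.1 Ohm reported for the CT anatomy.  Three
subject-specific observations are *not* reproduced, and the
corresponding acceptance expectations are deliberately left red rather
than papered over.

First, linearity of Z against fluid volume.  The first centimetre of
fluid sits level with the bottom electrode pair, where the two lead
fields barely overlap, and subsequent layers rise into the highly
sensitive zone between the rows, so `dZ/dV` grows with volume and the
curve is smoothly convex: r^2 is about 0.94 against the reference
0.997--0.9998, and the 300 mL impedance change is about 1.4 Ohm rather
than above 2 Ohm -- even though the average slopes (about -0.9 to -1.2
Ohm per 100 mL) are larger than the published ones (-0.47 to -0.75).
In the reference anatomy the lower lobes are evidently wide and deep
enough that successive volumes sample nearly constant sensitivity.

Second, contralateral isolation.  With fluid in the opposite lung the
reference saw changes within a 2 % band; the parametric torso is
laterally compact (the left lung's medial face sits about 1 cm from the
midline), so the right-side lead field reaches the contralateral lung
and the effect peaks near 6 %.

Third, side ordering: the cardiac notch makes the left lung about 17 %
smaller, so equal fluid volumes fill it proportionally higher; in this
geometry that outweighs the current-shunting influence of the
conductive heart, and the left side comes out *more* volume-sensitive
than the right -- the opposite ordering to the reference subject.

All three are properties of the deliberately simple anatomy, whose
parameters were fixed from the published volume targets and general
anatomical proportions; none was adjusted toward the reference
outcomes.  Passing the qualitative and identity tests shows that the
physics and the pipeline behave correctly, not that the parametric
anatomy reproduces subject-specific detail.

## Numerical choices and degenerate inputs

* Problem sizes: the experiment drivers default to `normal` refinement
  (about 4 x 10^5 elements); the qualitative trend checks in the test
  suite run at `coarser` (about 2 x 10^5), which the convergence study
  shows is within about 0.1 % of the fine-mesh impedance.
* Bisection for the fluid cut height runs at most 60 iterations over the
  lung height; a zero target is the identity and targets above 90 % of
  the lung volume are refused.
* Electrode patches must not overlap or leave the anterior surface;
  failures name the offending electrode.  A vertical-sweep offset that
  fails placement is flagged and the sweep continues.
* Ties in point location (points on cell faces) are resolved by a small
  barycentric tolerance; planar maps report NA outside the conductive
  domain and average over in-mesh samples only.
* Degenerate (non-positive volume) elements abort meshing with the
  offending region named; the structured construction makes them
  impossible for feasible geometries.

## Limitations

Homogeneous isotropic tissues; no skin layer, great vessels, respiratory
motion or posture dependence; fluid as a sharp horizontal interface
rather than a heterogeneous distribution; zero contact impedance.  These
mirror the scope of the modelling study the package operationalises and
are the natural extension points.
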