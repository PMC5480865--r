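---
title: "How much geometric detail does a figure-8 TMS coil model need?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How much geometric detail does a figure-8 TMS coil model need?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling question

Transcranial magnetic stimulation (TMS) drives a strong, briefly changing
current through a figure-of-eight coil held over the scalp; the changing
magnetic field induces an electric field in the cortex. Simulation studies
that predict this induced field must choose how faithfully to represent the
coil winding geometry, and practice varies from a single idealized circular
loop per coil wing to full stacks of spiral winding turns. `tmsfield`
implements the computational chain needed to quantify what that choice
costs: parametric coil generators, discretized Biot-Savart evaluation of
the magnetic field **B** and vector potential **A**, a pulse model mapping
stimulator settings to the scalar drive quantities, a quasi-static
finite-element (FEM) solve of the secondary field in a conductive head,
and a scalar cortical activation metric for comparing coil models.

Three coil models of increasing geometric fidelity are shipped as presets:

| preset   | geometry                            | segments/wing | distribution factor w |
|----------|-------------------------------------|---------------|------------------------|
| `bsm811` | one 44 mm circular loop per wing    | 92            | 7                      |
| `bsm819` | 9 spiral winding turns, 26–44 mm    | 763           | 1                      |
| `bsm879` | 7 stacked layers of the same spiral | 5341          | 1/7                    |

## Coil geometry

Each wing is generated from half-circles sampled over the angular range
0–π with a uniform angular step. The spiral wing chains
`2 * n_windings` half-circles whose radius grows by
`dr/2 = (outer_radius - inner_radius) / (2 * n_windings)` per half-circle;
the half-circle centers shift along x by the same amount with alternating
sign, which is the unique choice that makes consecutive half-circle
endpoints coincide. With the first center offset at zero, the first node
sits exactly at `inner_radius` from the wing origin and the last exactly at
`outer_radius`. The catalogue's per-wing segment totals (92, 763, 5341)
are apportioned across half-circles proportionally to radius
(largest-remainder rounding), keeping the arc length per straight segment
roughly uniform.

The two wings are mirror images through the y–z midplane and carry
opposite signed currents; the left wing's traversal order is reversed so
that the effective currents of the two wings run in the same direction
through the central region — the arrangement that gives the figure-8 its
focal spot. A flag (`central_reinforce`) exposes the handedness.

The stacked model distributes its layers symmetrically about the nominal
coil plane z = 0 at a configurable `layer_pitch` (default 1.0 mm; the
physical winding-pack pitch is not published and the field is insensitive
to it at stimulation distances). Centering matters: the stack represents
the *thickness* of the winding pack, and its mean plane must coincide with
the plane of the thin-coil models, otherwise the comparison between
stacked and flat spiral models is confounded by a net stand-off of half
the pack height. Per-layer current division (the `1/n_layers`
distribution-factor semantics) happens at field-evaluation time through
`w`, so the stacked path evaluated at `w = 1/n_layers` equals the average
of `n_layers` single-layer coils at their shifted heights.

All geometry is in SI meters; millimeter catalogue values are converted at
the preset boundary. The local coil frame is: coil plane z = 0,
subject-facing side −z, handle (long) axis y. `rigid_pose()` +
`apply_pose()` place a coil in world coordinates.

## Fields: discretized Biot-Savart

For a wire path carrying current I with distribution factor w,

- **B**(r) = μ₀ I w / 4π · Σ dl × (r − r₀) / |r − r₀|³
- **A**(r) = μ₀ I w / 4π · Σ dl / |r − r₀|

summed over sub-segments: each polyline segment is subdivided into
`ceiling(length/step)` equal pieces and the piece midpoint is the source
location r₀ (second-order accurate; endpoints versus midpoints is not
observable at the 1% tuning target, and the midpoint rule is what the
tuning procedure below validates). A negative segment current reverses the
traversal direction. Evaluation points closer than `min_distance`
(default `2 * step`) to any source midpoint raise an error rather than
returning a polluted value.

The discretization is tuned against the closed-form on-axis field of a
circular loop, μ₀ I R² / (2 (R² + z²)^{3/2}): a 44 mm loop discretized at
64 segments reproduces the analytic value at z = 1 cm within 1%
(`convergence_report()` tabulates the error against segment count and is
monotone under refinement). This closed form is the standard textbook
expression; `analytic_onaxis_loop()` implements it directly because any
dimensionally consistent on-axis loop formula must reduce to
μ₀I/2R at z = 0, which the 64-segment check confirms numerically.

## Pulse model

The stimulator delivers a biphasic pulse of one carrier cycle
(`frequency` 2500 Hz, `duration` 0.4 ms) with peak current 5500 A and peak
voltage 1650 V at 100% machine output (MO). Two scalar drive quantities
matter downstream:

- **Maximum dI/dt** drives the FEM: the linear ramp over the first quarter
  period, `MO * 5500 A / (1/(4f))`, giving 38.5×10⁶ A/s at 70% MO (and
  55×10⁶ A/s at 100%). A sinusoidal-slope alternative (2πf·I₀) is exposed
  behind a flag but is not the convention used for the reported values.
- **Equivalent DC current** drives the measurable field maps: the
  time-averaged integral of the damped biphasic waveform over the pulse,
  i.e. the constant current accumulating the same net MR phase. It is
  exactly zero for an undamped pulse and grows with the per-half-cycle
  `damping` factor. The real stimulator's damping coefficient is not
  published, so measured-equivalent currents (3576 mA for the spiral model
  at 1% MO) are treated as given inputs; the damped-sinusoid waveform
  `I(t) = I₀ e^{−λt} sin(2πft)` is provided for synthetic studies, with
  the closed-form integral cross-checked against trapezoidal quadrature in
  the tests.

The **current distribution factor** w rescales the drive so geometrically
different models deliver comparable ampere-turns: the single-loop model
uses the ratio of total wire length between the spiral and single-loop
geometries (≈ 7.06, applied as the integer 7), the spiral uses 1, and the
stacked model 1/7 per layer. Using the winding count 9 instead of the
length ratio would misstate the single-loop current by roughly 23%. Note
one internal inconsistency in commonly quoted drive tables: the single-loop
human-FEM dI/dt entry equals 7.5× the spiral value although the stated
rule is the ×7 wire-length factor; the package follows the stated rule.

## Quasi-static FEM

Under the quasi-static approximation the total induced field is
**Et = Ep + Es = −∂A/∂t − ∇Φ**. The scalar potential solves
∇·(σ∇Φ) = −∇·(σ ∂A/∂t) with the natural boundary condition
σ(∇Φ + ∂A/∂t)·n = 0 (no current leaves the head). Numerical choices:

- Linear (P1) tetrahedra with one-point quadrature; ∂A/∂t is sampled at
  mesh nodes (as `A` per unit current times the maximum dI/dt — the
  waveform is never time-stepped) and averaged to element centroids for
  the load. The assembled operator is symmetric positive semi-definite
  with zero row sums; the load sums to zero (pure-Neumann compatibility),
  both asserted in the tests.
- The singular constant mode is handled by deflation inside a
  Jacobi-preconditioned conjugate-gradient solver; the returned potential
  obeys the zero-mean gauge. Convergence is declared at relative residual
  RMS ≤ `tol` (default 10⁻⁴) — relative to the load RMS, since an absolute
  threshold would not survive unit changes. Non-convergence raises an
  error carrying the residual history.
- Per-element fields: `secondary = −∇Φ` is constant per tet; `primary` is
  the per-tet average of the four nodal −∂A/∂t values; `total` is their sum.

Tissue conductivities (S/m): scalp 0.5, skull 0.02, CSF 1.6, GM 0.3,
WM 0.25, phantom 1.6.

## Cortical activation metric

On a triangulated patch of the CSF↔GM boundary,
**Ec = Σᵢ Sᵢ |Etᵢ · nᵢ|** (units V·m), with Sᵢ the triangle area and nᵢ
the outward unit normal (GM into CSF, the direction of pyramidal-cell
axons). The left-hand side is a scalar: the area-weighted absolute normal
flux, reported as a single activation proxy per coil model and
orientation. Fields are sampled at triangle centroids by barycentric
interpolation of nodal values (per-element fields are first
volume-averaged to the nodes). The hemisphere-in-uniform-field closed form
(Σ S|cosθ| → πr²·U) anchors the implementation in the tests, and Ec is
invariant under rigid motion and linear in the field scale.

`extract_patch()` masks a surface to an ROI, keeps the largest
edge-connected component (reporting dropped islands) and recomputes areas
and outward normals.

## Synthetic fixtures: what they emulate, and what they do not

No measurement data or subject mesh ships with the package; all test
inputs are generated:

- `make_phantom_grid()`: voxel centers of a 12.5 cm × 20 cm upright
  cylinder (the agar phantom) at the 1×1×2 mm scan resolution by default.
- `make_sphere_head()`: a five-shell concentric-sphere head
  (WM/GM/CSF/skull/scalp with outer radii 70/78/82/86/92 mm — standard
  concentric head-model values, chosen because the real segmented head
  mesh is not distributable). The mesh is built radially from subdivided
  icosahedra joined by prisms split into three tetrahedra along
  index-ordered diagonals, which keeps faces conforming and the outer
  boundary watertight.
- `make_gyrus_patch()`: a sheet z = a·cos(2πx/λ) standing in for a gyrus
  with ridges along y, the testbed for the orientation effect (coil handle
  across the ridge versus along it).
- `synth_measurement()`: truth + iid Gaussian noise (default σ = 5×10⁻⁷ T,
  a plausible MR phase-noise floor) with voxels masked where |Bz| exceeds
  the over-phasing bound π/(γτ) ≈ 2.9×10⁻⁵ T (γ the proton gyromagnetic
  ratio, τ the 0.4 ms pulse), emulating the near-coil signal dropout of
  phase-map field measurements. All randomness sits behind an explicit
  seed.

These fixtures reproduce the *structure* of the validation problem —
near-coil dropout, a noise floor at depth, inter-model field differences
concentrated under the coil — but not the anatomy of a segmented head,
the exact winding layout of the physical coil, or MR acquisition physics
(no spin-echo simulation, no phase unwrapping, no co-registration error).
Passing tests on them therefore certify the machinery and the relative
orderings (single-loop vs spiral vs stacked, orthogonal vs parallel), not
the absolute percentages a real head and coil would produce.

## Problem sizes and tolerances used by the test suite

The test and acceptance runs use sphere meshes at target edge lengths of
30/20/15 mm (up to ~1.4×10⁵ tets), a 5 mm phantom grid, and a 2 mm
Biot-Savart integration step for volume sampling — sizes chosen so the
full pipeline (three coil models × two orientations, solved to residual
10⁻⁴–10⁻⁶) completes in tens of seconds while leaving the asserted
orderings far from their thresholds. The shipped preset integration steps
(0.012–0.04 mm) reproduce the catalogue configuration and are intended
for production field maps, not for the test suite.

## Known limitations

- Isotropic conductivities only; no tensor anisotropy, dispersion or
  capacitive effects.
- Equal current split across windings and layers (deliberate; non-uniform
  schemes are out of scope).
- No litz-wire cross-section or skin-effect modelling; the wire is a
  polyline.
- The activation metric is a macroscopic proxy; it contains no membrane
  biophysics and is not an MEP predictor.
- The concentric-sphere head and sinusoidal gyrus are stand-ins; absolute
  inter-model percentages on real anatomy are outside what this package
  can certify.
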