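# tmsfield

Simulation tools for asking a practical question in transcranial magnetic
stimulation (TMS) modelling: **how much geometric detail does a
figure-of-eight coil model need** before predictions of the induced
cortical electric field stop changing? The package is aimed at
computational neurostimulation researchers who run finite-element E-field
simulations and need to decide between idealized and realistic coil
representations.

## What it computes

Three figure-8 coil models of increasing fidelity are generated as
discretized wire paths (presets `bsm811`, `bsm819`, `bsm879`): a single
44 mm circular loop per wing, a single layer of nine spiral winding turns
(26–44 mm), and seven stacked layers of that spiral. From a wire path the
package evaluates, by piecewise Biot-Savart integration,

- the magnetic field **B**(r) = μ₀Iw/4π · Σ dl × (r−r₀)/|r−r₀|³, and
- the vector potential **A**(r) = μ₀Iw/4π · Σ dl/|r−r₀|,

where the distribution factor *w* (7, 1, 1/7) rescales the drive current
so the three geometries deliver comparable ampere-turns. A pulse model
converts stimulator settings (biphasic 2.5 kHz, 0.4 ms, 5500 A / 1650 V at
100% machine output) into the equivalent DC current for field maps and the
maximum dI/dt (38.5×10⁶ A/s at 70% MO) that drives the quasi-static FEM

Et = Ep + Es = −∂A/∂t − ∇Φ,  with ∇·(σ∇Φ) = −∇·(σ ∂A/∂t),  σ(∇Φ+∂A/∂t)·n = 0,

solved with P1 tetrahedra and deflated Jacobi-preconditioned conjugate
gradients on labeled meshes (scalp/skull/CSF/GM/WM). Coil models are
compared through the cortical activation metric

Ec = Σᵢ Sᵢ |Etᵢ · nᵢ|  (V·m)

over a gray-matter surface patch, and through absolute-difference maps
|Bz_measured − Bz_simulated| against (synthetic) field measurements.
Fixture generators provide a cylindrical phantom grid, a five-shell
concentric-sphere head mesh, a sinusoidal gyrus patch and noisy
pseudo-measured Bz maps with near-coil dropout. See the methods vignette
(`vignettes/coil-detail-modelling.Rmd`) for the model details and design
choices.

## Worked example

Build the spiral coil, check the discretization, solve the FEM chain on
the sphere-head fixture and evaluate the activation metric:

```r
library(tmsfield)

spec <- coil_preset("bsm819")
coil <- build_spiral_figure8(spec)
coil
#> wire_path: 1528 nodes, 1526 segments, |I| = 1 A, length 3.9009 m

convergence_report(0.044, 0.01, c(8, 16, 32, 64))
#>   segments   rel_error
#> 1        8 0.127411375
#> 2       16 0.029895644
#> 3       32 0.007359351
#> 4       64 0.001832792

drive_report(pulse_spec(), 0.70, w = spec$distribution_factor)$max_didt_As
#> [1] 3.85e+07

mesh <- make_sphere_head(target_edge = 0.02)
patch <- translate_patch(make_gyrus_patch(0.02, 0.02, 0.003, 0.01, 0.002),
                         c(0, 0, 0.073))           # ROI inside the GM shell
path <- apply_pose(coil, rigid_pose(rot_z(pi / 2), c(0, 0, 0.098)))  # 2 cm over GM

A <- vector_potential(path, mesh$nodes, current = 1, w = 1,
                      cfg = integration_config(2e-3, 1e-3))
dAdt <- A$vectors * (max_didt(pulse_spec(), 0.70) * spec$distribution_factor)
sol <- solve_potential(assemble_system(mesh, dAdt))
sol
#> potential_solution: 5137 nodes, residual 8.8e-05 after 64 iterations

ef <- total_efield(mesh, sol, dAdt)
ec_metric(patch, sample_field_on_patch(ef, mesh, patch))
#> metric_result: Ec = 0.0192725 V m over 6.228 cm^2 (200 triangles)
```

The wire length 3.9009 m is ≈ 7× the single-loop model's 0.5528 m — the
origin of the single-loop distribution factor. The 64-segment row of the
convergence report (0.18% at 1 cm) is the discretization tuning check.
The median |Et| of ~4 V/m in the volume and the Ec value compare coil
models once repeated for each preset and orientation (`run_brain()`
automates the chain; `compare_models()` reports relative differences).

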