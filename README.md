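# thoraximp

Finite-element forward modelling of **tetrapolar (four-electrode)
transfer impedance** on the human thorax, for assessing electrical
bioimpedance as a non-invasive, non-ionizing monitor of **pulmonary
fluid accumulation** (pulmonary edema, pneumonia).  The package is aimed
at bioimpedance and biomedical-instrumentation researchers who want a
fully scripted, reproducible stand-in for CAD/commercial-solver
pipelines: a parametric thorax instead of segmented CT anatomy, a
deterministic mesher, and a quasi-static conduction solver, all in R.

## The model

The potential in the thoracic volume conductor obeys the quasi-static
conduction equation

    div( kappa grad V ) = 0,        kappa = sigma + i 2 pi f eps0 eps_r

with insulating outer boundary and airway walls (J·n = 0).  Current
I0 = 1 mA is injected through electrode pair A–B (terminal condition:
the patch is an equipotential carrying total current ∫S J·n dS = I0, the
return patch is ground), and a second, reciprocal lead field is driven
through the sense pair C–D.  The local **volume impedance density**

    z = (1/kappa) (J_AB · J_CD) / I0^2        [Ohm/m^3]

integrates to the tetrapolar transfer impedance Z = ∫ z dv, identically
equal (in the discrete system) to the conventional reading
Z = (V_C − V_D)/I0 on the floating sense patches.  z maps *where* the
measurement is sensitive, and its per-region sums give each organ's
contribution to Z.

The synthetic thorax is an elliptic-cylinder torso (volume pinned to
23.4 L) containing truncated-ellipsoid lungs auto-scaled to 4.84 L
total, an ellipsoid heart left of midline, 12 rib pairs, insulated
airways, and a gravity-pooled fluid region carved into a lower lobe by a
horizontal cut plane found by bisection.  Electrodes are four 1 cm
discs on an 8 cm square on the chest surface; at the reference position
the bottom pair is level with the lower lung margin.

## Worked example

```r
library(thoraximp)

geom <- build_geometry(thorax_params())        # 23.4 L torso, 4.84 L lungs
geom <- carve_fluid_region(geom, "right", 670e-6)
geom <- place_electrode_array(geom, "right")   # 8 cm square, lower right
print(geom)

r <- thorax_impedance(geom, solve_spec(), refinement_level = "coarser")
round(r$Z, 3)
round(c(lungs = regional_contribution(r$field, c("lung_right", "lung_left")),
        fluid = regional_contribution(r$field, "fluid")), 3)
```

```
Synthetic thorax geometry
  torso: 0.149 x 0.100 m semi-axes, height 0.500 m, volume 23.40 L
  lungs: 2.20 L (left) + 2.64 L (right)
  heart: 0.67 L; ribs: 12 pairs; airways: on
  fluid (right lung): 670 mL up to z = 0.263 m
  electrodes: right side, offset 0.000 m, separation 0.080 m
[1] 9.056
lungs fluid 
3.428 0.943 
```

With 670 mL of fluid pooled in the right lower lobe the impedance at
the right lower electrode position drops from about 14.5 Ohm (healthy
baseline) to 9.1 Ohm: conductive fluid (1.5 S/m) has displaced
resistive inflated lung (0.093 S/m) in the most sensitive zone under
the array.  The regional decomposition shows the remaining inflated
lung tissue contributing 3.43 Ohm and the fluid region itself 0.94 Ohm
of the 9.1 Ohm total.

Experiment drivers reproduce the study protocols end to end:
`vertical_sweep()` (2 cm steps of the array), `fluid_volume_sweep()` +
`linear_fit_volume()` (Z vs 0–670 mL, slope in mOhm/100 mL),
`frequency_sweep()` (5–1000 kHz, complex admittivity),
`mesh_convergence_study()` (four refinement levels), with
`percent_delta_Z()` and `detectability_band()` for the ±2 %
measurement-variability analysis.  `run_command()` exposes the same
drivers as shell-style subcommands writing delimited result tables,
VTK field exports and run logs.

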