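# iolglare

Non-sequential ray tracing of photic phenomena (positive dysphotopsia) in
the pseudophakic eye.

After cataract surgery, oblique light from the far temporal visual field
can reach the retina along paths that have nothing to do with ordinary
imaging: transmitted through the truncated cylindrical **edge** of the
intraocular lens (IOL) optic, internally reflected at that edge, or passed
through the annular **interspace** between the iris margin and the optic.
The bright arcs and crescents these paths produce are a common source of
patient complaints, and their geometry depends on the IOL's optic diameter
and edge finish. `iolglare` is a research tool for exploring exactly that
dependence: it is aimed at physiological-optics and ophthalmic-device
researchers who want a scriptable, fully auditable alternative to
commercial non-sequential tracers for this class of problem.

## What it computes

The package assembles a Liou–Brennan-based pseudophakic schematic eye —
aspheric cornea (R 7.77/6.40 mm, k −0.18/−0.60, n 1.376), 4.5 mm pupil
decentred 0.5 mm nasally, an IOL (front sphere R 13.86 mm; back even
asphere R −11.66 mm, k −1.5, α₂…α₈ polynomial; n 1.458; optic diameter 6
or 7 mm; six edge designs) and a spherical detector retina (R −12 mm,
axial length 23.95 mm). A non-sequential engine traces collimated
extended-source bundles through it with deterministic Fresnel ray
splitting, total internal reflection, and absorbing / mirror /
anti-reflecting / Lambertian-frosted / knife-thin edge idealizations,
under a strict energy ledger (closure to 1e−9). Retinal hits are binned
into irradiance maps layered by interaction path (`direct`, `interspace`,
`edge_transmitted`, `edge_reflected`, `other`), and search procedures
locate the fovea, the critical incidence angles at which edge light is
maximally foveal, and the onset angle of the interspace pattern.

The sag convention is the standard even asphere,
z(r) = c r² / (1 + √(1 − (1+k) c² r²)) + Σᵢ α₂ᵢ r²ⁱ with c = 1/R; note
that the α₂ term contributes to the paraxial curvature (1/R_eff = 1/R +
2α₂), which is what makes the Table-style IOL prescription come out at its
labeled 21 D.

## Worked example

```r
library(iolglare)

eye <- build_model(6, "standard")
print(eye)
#> Pseudophakic schematic eye (non-sequential object list)
#>   IOL optic diameter : 6.0 mm, edge mode 'standard'
#>   Edge rim gap       : 0.2943 mm
#>   Pupil              : 4.50 mm diameter, hole centre x = -0.50 mm
#>   Axial length       : 23.95 mm (retina R -12.0 mm)
#>   ...

locate_fovea(eye)
#> [1] 1.426770     # mm temporal of the posterior pole

sw <- angle_sweep(optic_diameter = 6, angles = seq(50, 70, 5), n_rays = 2e4)
round(sw$table[, c("angle", "retina_total", "retina_interspace",
                   "retina_edge_transmitted", "retina_edge_reflected")], 5)
#>   angle retina_total retina_interspace retina_edge_transmitted retina_edge_reflected
#> 1    50      0.54086           0.04865                 0.02232               0.00564
#> 2    55      0.51152           0.06547                 0.02926               0.00309
#> 3    60      0.47882           0.08370                 0.03498               0.00141
#> 4    65      0.44416           0.10511                 0.03787               0.00081
#> 5    70      0.20346           0.00000                 0.03817               0.00050

find_onset_angle(6, angles = seq(50, 70, 5), sweep = sw)
#> Interspace onset angle: 50 deg (floor 1e-06)
```

Reading the table: at 50° incidence about 54 % of the source energy
reaches the retina, of which 4.9 % arrived through the iris–IOL interspace
and 2.2 % through the optic edge; by 70° the interspace channel has closed
(its rays exit through the retinal equator) while edge transmission
persists. With the 7 mm optic the interspace pattern first appears at 55°
instead of 50° — the narrower iris–optic channel admits only steeper rays.
Maps for any run are available via `bin_hits()`, exported with
`write_retina_map()` or rendered with `render_retina_map()`;
`edge_comparison()` contrasts all six edge designs at one angle, and
`find_critical_angle()` searches the 50–90° range for the angle whose
edge-tagged light is maximally foveal.

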