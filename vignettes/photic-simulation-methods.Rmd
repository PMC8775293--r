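---
title: "Simulating pseudophakic photic phenomena: model, methods and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pseudophakic photic phenomena: model, methods and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iolglare)
```

## The problem

After cataract surgery some patients report bright arcs, streaks or halos
(positive dysphotopsia) that do not correspond to any imaged object. The
accepted optical explanation is stray light interacting with the implanted
intraocular lens (IOL): oblique light from the far periphery of the visual
field can be transmitted through or internally reflected at the truncated
cylindrical *edge* of the IOL optic, or can pass through the annular channel
between the iris margin and the optic (the iris–IOL *interspace*), and land
on the retina far from the ordinary image. `iolglare` simulates this
situation end to end: it builds a pseudophakic schematic eye, traces
collimated oblique ray bundles through it non-sequentially, maps the retinal
irradiance separated by interaction path, and searches for the incidence
angles at which edge-related light falls on the fovea.

## The eye model

The geometry is the Liou–Brennan schematic eye with the crystalline lens
replaced by an IOL, assembled by `build_model()`:

| object | radius (mm) | conic | vertex z (mm) | aperture (mm) |
|---|---|---|---|---|
| cornea front | 7.77 | −0.18 | 0.00 | 14 |
| cornea back | 6.40 | −0.60 | 0.50 | 14 |
| iris stop | ∞ | — | 3.66 | hole 4.5, annulus to 14 |
| IOL front | 13.86 | 0 | 4.29 | 6 or 7 |
| IOL back | −11.66 | −1.5 (+ α₂…α₈) | 5.26 | 6 or 7 |
| retina | −12 (half-sphere) | — | apex 23.95 | 24 |

Indices: air 1.0, cornea 1.376, aqueous and vitreous 1.336, IOL 1.458, all
at a single design wavelength (the published model gives constant indices
and no dispersion data). The pupil hole is decentred 0.5 mm nasally. The
back IOL surface is an even asphere with polynomial coefficients
α₂ = −6.34·10⁻³ mm⁻¹, α₄ = 1.15·10⁻³ mm⁻³, α₆ = −3.86·10⁻⁷ mm⁻⁵,
α₈ = −2.47·10⁻⁸ mm⁻⁷ on top of the conic term. Axes: light travels in +z,
nasal is −x, temporal +x; results are mirror-symmetric to the opposite
chirality.

Two derived facts are worth recording because they validate the
prescription. First, the paraxial curvature of an even asphere is
1/R + 2α₂, so the back surface acts paraxially like R_eff = −10.16 mm; with
that, the IOL's thick-lens power in aqueous is 20.7 D (matching its 21 D
label, which a naive 1/R calculation misses) and the eye's paraxial focus
lands 0.16 mm in front of the retinal apex. Second, the geometric rim gap
between the two optic surfaces at the optic radius — the height of the edge
cylinder — is 0.294 mm for the 6 mm optic (the nominal "0.3 mm edge") but
only 0.095 mm for the 7 mm optic: a single shared prescription cannot give
both optics the same edge thickness. We build what the prescription
implies rather than forcing the nominal value, which would break surface
continuity.

## Edge designs

`build_model(optic_diameter, edge_mode)` supports six edge designs. The
*standard* edge is a bare polished dielectric cylinder (Snell refraction
plus Fresnel reflection, like the optic surfaces). *Absorbing* terminates
rays; *reflecting* is an ideal mirror; *anti-reflecting* transmits with the
Fresnel reflectance forced to zero; *frosted* diffuses both Fresnel
portions (cosine-weighted Lambertian hemisphere sampling by default, with a
documented uniform-in-solid-angle "isotropic" switch, since both models are
used in the literature for frosted surfaces); *thin* extends both optic
surfaces to their intersection radius, forming a knife edge with no edge
surface at all. Two idealizations deserve a note. An anti-reflecting
coating cannot physically defeat total internal reflection; to keep the
idealization exactly reflection-free (its defining property here), edge
rays beyond the critical angle are booked as absorbed. And the thin design
necessarily changes the optic outline (its aperture grows to the knife
radius, ≈ 3.8 mm), so quantities that depend on the iris–IOL channel
geometry — notably the interspace pattern — legitimately differ between the
thin and the thick designs.

## The tracing engine

`trace()` is a non-sequential engine: each ray repeatedly intersects the
*nearest* forward object, whatever it is. Intersections with conic
surfaces use the closed-form quadric solution; the polynomial asphere is
solved by Newton iteration seeded with the conic roots (tolerance 10⁻⁹ mm,
at most 50 iterations, launch epsilon 10⁻⁶ mm against self-intersection;
non-converged candidates count as misses and are reported). At dielectric
interfaces rays split deterministically into a transmitted and a reflected
child carrying the unpolarized Fresnel energy fractions — reproducible maps
with no Monte-Carlo noise on specular paths. Termination: retina hit,
absorption, escape, energy below 10⁻⁴ of the mean initial ray energy, split
generation beyond 8, or (as a loop guard) more than 64 interactions. The
frosted edge spawns 8 scattered children per Fresnel portion, seeded from
the trace policy — the only stochastic element in the pipeline.

Every trace carries an energy ledger (emitted = retina + absorbed by object
+ escaped + cutoff) that must close to 10⁻⁹ relative or the run aborts.
Each retinal hit records the ray's interaction counters, from which a
disjoint path class is derived with precedence: any edge reflection →
`edge_reflected`; else any edge crossing → `edge_transmitted`; else pupil
passage without optic contact → `interspace`; else pupil passage with optic
contact → `direct`; everything else (e.g. rare rays entering around the
iris annulus through the corneal rim) → `other`. Requiring a pupil pass
for `interspace` keeps the onset detection below clean of such strays.

## Sources, retinal maps, experiments

The glare source (`make_bundle`) is a collimated pencil from a 6 mm disc
perpendicular to its propagation direction, aimed at the pupil-hole centre
from the temporal side, with the incidence angle measured from the optical
axis; total energy is normalized to 1. The default layout is a
deterministic sunflower grid so that every reported number is free of
Monte-Carlo noise; a seeded uniform layout is available. The source
distance (15 mm standoff) and aim point are package choices — the reference
description does not state them — and are configurable for sensitivity
checks. The fovea is localized (`locate_fovea`) as the retinal centroid of
a narrow bundle entering 5° nasally through the pupil centre, the
physiological angle between visual and optical axis; it lands 1.43–1.44 mm
temporal of the posterior pole. The foveal region of interest is a disc of
radius 0.75 mm (≈ 1.5 mm foveal diameter, the standard anatomical figure)
around that point.

Retinal hits are projected azimuthal-equidistantly about the posterior pole
(arc-length coordinates, area-faithful near the fovea) and binned at
0.05 mm into one irradiance layer per path class (`bin_hits`); maps export
as delimited grids with metadata headers and render to PNG. Experiments:
`angle_sweep` traces the 50–90° grid in 5° steps; `find_critical_angle`
maximizes the foveal-ROI energy of an edge class over angle (coarse 5°
scan, then nested grid refinement at 1, 0.25 and 0.05° — robust against
the non-smooth, sometimes empty objective, unlike golden-section);
`find_onset_angle` reports the first grid angle whose interspace layer
exceeds 10⁻⁶ of the emitted energy; `edge_comparison` runs all six designs
at one angle and asserts their definitional exclusions.

```{r quick-example, eval = FALSE}
eye <- build_model(6, "standard")
fovea <- locate_fovea(eye)
sweep <- angle_sweep(optic_diameter = 6, n_rays = 1e5)
find_onset_angle(6, sweep = sweep)   # -> 50 degrees
```

## What reproduces, what does not, and why

Run at the study conditions (deterministic 6 mm disc source, 10⁵ rays per
angle), the model reproduces without any tuning: the temporal foveal
offset (1.43 vs the published 1.462 mm, within 0.04 mm); the interspace
onset angles exactly — 50° for the 6 mm optic and 55° for the 7 mm optic,
including the mechanism for the 7 mm delay (the narrower channel admits
only steeper rays, and at 50° the few that pass exit through the retinal
equator plane before reaching the detector half-sphere); the paraxial
focus; and the 21 D power label. These quantities jointly pin the angle
convention (from the optical axis) and the chirality (temporal source,
nasal pupil decentration): every alternative reading we tested breaks the
onset ordering or moves the onsets by 20°.

The published *critical angles* for the foveal photic arc (77.5°/78.2°
standard edge, 67.4°/68.8° fully reflecting edge) do **not** reproduce in
this geometry, and the package's searches report that honestly. The
reason is geometric, not statistical: through-pupil rays at 50–90°
incidence reach the retina at internal obliquities ≥ 45° and land ≥ 14 mm
(arc) nasal of the pole, while the edge-internal-reflection path exits
≥ 8 mm temporally; a 10⁶-ray trace at 77.5° deposits zero energy of any
class within 2.5 mm of the fovea. The only edge-related pattern that
crosses the foveal ROI in this model is the internal-reflection (TIR) arc
at ≈ 26° incidence — far below the 50–90° sweep — and there the standard
and mirror edges are identical (total internal reflection *is* mirror
reflection), which also rules out two distinct critical angles for the two
designs. We conclude that some unstated aspect of the original
non-sequential setup differs from the published prescription; the search
procedure itself remains fully functional and is exercised over the 50–90°
grid, where it finds only faint stray-light maxima (≈ 5·10⁻⁷ of the source
energy, near 84–89°) for the standard edge and an empty objective for the
reflecting edge.

The frosted edge behaves as expected qualitatively: at equal ray budget it
reduces the peak edge-layer bin irradiance by roughly two orders of
magnitude while leaving the Fresnel-split energy leaving the edge exactly
unchanged (by construction). Its *retinal* edge-layer total is however
only 15–20 % of the standard edge's: hemispheric diffusion sends most edge
light onto the iris rear or out of the eye. Contrast reduction on the
retina therefore comes with a real intensity loss in this model, a
distinction the acceptance suite makes explicit.

## Numerical choices and limitations

Intersection tolerance 10⁻⁹ mm and the 10⁻⁶ mm launch epsilon are set by
double precision at eye scale; the energy cutoff 10⁻⁴ and generation cap 8
bound the deterministic split tree (ledger closure verifies nothing
physical is lost above those floors). Accumulation is plain double
summation; traversal order does not affect results beyond floating-point
addition order. Simulation sizes in the tests and the acceptance script
(10⁵ rays per angle for sweeps and coarse searches, 5·10⁴ for refinement,
4·10³ for fovea localization) were chosen as the points where the reported
quantities are stable to well inside their tolerances (e.g. doubling the
fovea bundle moves the centroid < 0.01 mm; doubling the search budget moves
a located angle < 0.2°).

Not modeled: polychromatic dispersion, polarization and coherence,
haptics, IOL tilt/decentration, toric or multifocal optics, retinal
sensitivity weighting and any perceptual stage — the maps are radiometric,
in relative units. The synthetic source emulates a distant glare point
through a 6 mm aperture stop; real glare sources are extended and
polychromatic, so passing tests here demonstrate geometric-optical
behaviour of the model, not clinical visibility of any pattern.
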