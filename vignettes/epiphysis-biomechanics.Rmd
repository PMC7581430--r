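---
title: "Mechanics of the growing epiphysis: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of the growing epiphysis: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimech)
```

## The scientific question

During postnatal growth, bone elongation happens in the growth plate, a thin
cartilage disc whose hypertrophic chondrocytes are mechanically fragile. In
mammals the cartilaginous bone end (epiphysis) develops a secondary
ossification center (SOC) above the growth plate; in some extinct and extant
tetrapod lineages the same region instead carries ossified protrusions
penetrating the epiphyseal cartilage. `epimech` implements the quantitative
machinery needed to study whether such stiff structures mechanically shield
the growth plate: a parametric plane-strain finite-element model of the
epiphysis with swappable stiff subdomains, post-processing into the stress
measures relevant for cell survival, analysis of ex-vivo mechanical tests,
Hertzian fitting of AFM/nanoindentation force curves, and allometric
pressure-scaling calculations.

## The finite-element model

### Geometry

The domain idealises a long-bone end as a 2D plane-strain section: a
semicircular cartilaginous head (radius 17 mm) on a trapezoidal shaft (total
height 66 mm, bottom width 25 mm), with 2.5 mm cortical walls, a horizontal
growth-plate band, metaphyseal bone below it, and a candidate stiff region
inside the head. The out-of-plane thickness is 1 mm by definition. Five
subdomains are always present (`subdomain_labels()`); four variants differ
only in the shape and material of the stiff region:

* `with_soc` — a semi-elliptical SOC insert (default semi-axes 12 x 8 mm,
  centered at height 53 mm);
* `no_soc` — identical polygons, but the insert is assigned the cartilage
  material, so with/without comparisons are mesh-identical;
* `protrusions_small` / `protrusions_extended` — the insert is replaced by
  stadium-shaped (rounded-end) fingers rising into the cartilage (defaults:
  5 fingers, 2 mm wide, 5 mm spacing, depths 4 and 10 mm).

Dimensions not printed anywhere were fixed once on anatomical grounds and are
configurable through `epiphysis_params()`: the band is 3 mm tall centered at
42 mm, and every stiff element keeps a 1.5 mm cartilage layer between its
base and the band top, so the evaluated hypertrophic band is free of bony
elements in all variants. Finger ends are rounded because biological
ossified protrusions are; sharp inclusion corners would inject artificial
stress singularities into the soft band below them.

### Meshing

`generate_mesh()` triangulates the labeled polygons with an in-package
Bowyer-Watson Delaunay kernel: polygon rings are resampled at the target
edge length (points on the head arc and the insert ellipse are placed on the
analytic curves), interior points come from a hexagonal lattice, and each
polygon keeps the triangles whose centroid falls inside it. Interfaces are
shared point-for-point, so the mesh conforms to every material boundary.
Subdomain polygons are built as half-domain pieces split on the symmetry
axis and the left half is meshed by exact reflection of the right, which
makes the discrete model mirror-symmetric to machine precision — vertical
loads then produce exactly symmetric fields, a property the test suite
checks at 1e-6 of the field norm. Triangles are elevated to 6-node
quadratic elements (midside nodes projected onto curved boundaries); the
near-incompressible cartilage (nu = 0.47) would lock badly with linear
triangles.

### Materials, loads, boundary conditions

All subdomains are linearly elastic in the constitutive sense: cartilage
E = 6 MPa, nu = 0.47; the stiff insert E = 500 MPa, nu = 0.20 (dense
cancellous bone, about eighty-fold stiffer than cartilage). Cortical
(E = 5000 MPa, nu = 0.30) and metaphyseal (same as the insert) values are
reconstructions — they sit far from the band and barely influence its
stresses — and are configurable via `material_map()`.

The load is a pressure on a 45-degree sector of the head arc, maximal at the
sector center (0.3 MPa physiological, 3 MPa supra-physiological) and falling
quadratically to zero at the sector borders. The phrase "to zero on the two
neighboring sector borders" admits a wider reading (support spanning the two
neighbouring sectors, 135 degrees in total); both are implemented
(`wide_support`), with the 45-degree support as default. By default the
pressure is a follower load on the deformed surface — consistent with the
observation that the direction and integrated force of loading are slightly
affected by the finite deformation — with a dead-load option for comparison.
The bottom edge is fixed vertically and the outer cortical edges
horizontally.

### Solver

`solve_elasticity()` uses total-Lagrangian kinematics with the Saint
Venant-Kirchhoff law (stress linear in Green-Lagrange strain — "linear
materials, non-linear strains") and solves by incremental Newton iteration:
10 equal load increments at supra-physiological levels (1 at physiological),
relative residual tolerance 1e-8, a backtracking line search on the residual
norm, a secant predictor between load steps, and automatic step bisection
(up to 6 times) on failure. Element integration uses the 6-point degree-4
rule; the minimal 3-point rule admits near-spurious modes at finite strain.
Tangent systems are solved with CHOLMOD (the `Matrix` package), falling back
to sparse LU if a tangent stops being positive definite. A small-strain
option supports verification against closed-form linear solutions (uniform
block compression, patch test) and the low-load linearisation check.

### The supra-physiological load limit

A genuine property of this model class deserves emphasis: the Saint
Venant-Kirchhoff law softens under finite compression, and the nominal
uniaxial compressive stress it can transmit is bounded by
`0.385 E / (1 - nu^2)`, about **1.48 MPa** for the cartilage constants.
Accordingly the quasi-static equilibrium branch of the epiphysis model ends
at a limit point near **1.4 MPa peak sector pressure** — mesh refinement
(h = 2.0 to 0.45 mm), the 45 vs 135-degree support reading, and follower vs
dead loading all leave it in place, and both damped-Newton and
Levenberg-regularised continuation confirm that no nearby static solution
exists beyond it. The 3 MPa "supra-physiological" case therefore has no
converged finite-strain equilibrium in this formulation; the solver reports
the last converged load fraction instead of fabricating a state. Variant
comparisons in the test suite run at 1.2 MPa — four times physiological and
safely below the limit point — and at the physiological 0.3 MPa.

### What the model reproduces

At statically sustainable loads the model reproduces, and the test suite
asserts, the following:

* the SOC stiffens the whole joint structure: its load-sector deflection is
  far below that of the SOC-free model, while ossified protrusions leave the
  overall deflection within 20% of the SOC-free model (they do not improve
  structural stiffness);
* under angled (45-degree) loading, both the SOC and extended protrusions
  lower the area-weighted octahedral shear stress in the growth-plate band;
* under vertical loading the SOC raises the hydrostatic (volumetric)
  compression of the band — the confined, well-tolerated stress state —
  and hydrostatic compression is elevated in the central third of the band;
* under a 45-degree load applied from the right at the physiological level,
  the most compressive principal stress in the band occurs in the left
  third, matching the lateralised chondrocyte death observed opposite the
  loaded side.

Raw band-wide *peak* octahedral shear, by contrast, is dominated by local
concentrations (under finger bases, at material corners) and does not order
the variants cleanly in this reconstruction; the distribution-level measures
above are the robust signal. Stress is reported as the second
Piola-Kirchhoff tensor relative to the unstressed reference volume, at
element quadrature averages with no nodal smoothing, so zone summaries are
never diluted across material interfaces. The out-of-plane component
`S33 = lambda (E11 + E22)` enters all three scalar measures (hydrostatic,
lowest principal, octahedral shear), which are 3D stress-state measures.

## Mechanical-test analysis

`deformation_series()` zeroes the instrument position at the contact point
(interpolated at a 2% of peak-load threshold; no machine-compliance
correction is applied). `stiffness_fit()` defines the "initial linear
portion" reproducibly: candidate windows of several lengths (at least 20% of
the samples) confined to the first half of the load range are scored by
R-squared, which rewards the longest single-regime window; the measured
(noisy) position is regressed on the programmed load and the slope inverted,
avoiding regression-dilution bias. Stress distributes the load over the
oval loaded surface (`pi d1 d2 / 4`, top diameters for vertical loading,
side diameters for angled), strain distributes deformation over the
epiphysis height, and `offset_yield()` intersects the 0.2% offset line with
the measured curve — on a lightly smoothed curve with a persistence check,
because measured strain noise is comparable to the 0.002 offset. On 200
synthetic bilinear records with 1% position noise, median recovery error is
below 2% for stiffness and 3% for yield strength.

## Hertzian indentation fitting

Force-distance curves (AFM colloidal probes, k = 0.06-0.09 N/m, R = 5 um,
retract curves; or a spherical nanoindenter, k = 4.14 N/m, R = 45.5 um, 5 um
immersion) are converted to indentation by subtracting the cantilever
deflection from the piezo travel (AFM) and fitted to
`F = (4/3) E/(1-nu^2) sqrt(R) delta^(3/2)`. The contact point is fitted
jointly with the modulus — for a candidate contact point the modulus is a
closed-form least-squares value, and the profiled residual is minimised over
a contact-point bracket anchored at the force transition (this bracket
removes a degenerate residual minimum in which the whole contact branch
would be excluded from the fit). Only non-negative forces enter the fit
(adhesion wells are excluded); indentation is capped at 10% of the probe
radius (AFM) or 5 um (nanoindenter). The sample Poisson ratio is not
identifiable from a single curve and defaults to 0.5 (incompressible),
reported with every fit. No bottom-effect (finite-thickness) correction is
applied. Aggregation supports pooled mean +/- SD and per-unit medians (the
robust choice for skewed indentation maps). Parameter-recovery tests: exact
to 0.1% on noiseless curves, median error below 5% at 2% force noise.

## Allometric scaling

With stylopod diameter scaling as `D = k BM^a`, growth-plate pressure
(load per cross-sectional area) scales as `BM^(1-2a)`. `pressure_fold()`
evaluates this for the published exponents (0.364 combined tetrapods, 0.366
ungulates, 0.3944 insectivores/rodents): a thousandfold mass increase raises
growth-plate pressure 4.3- to 6.6-fold, while `a = 0.5` would compensate
completely. Only mass and diameter *ratios* are unit-safe; the combined
regression's coefficient (k = 1.26) carries its source units. Reported folds
are rounded to one decimal only at the reporting layer.

## Synthetic data

Every analysis input can be generated with known ground truth:
`gen_force_curves()` (Hertzian contact plus additive Gaussian force noise,
default 2% of full scale), `gen_load_deformation()` (bilinear
elastic/post-yield record at 0.1 N/s with Gaussian position noise, default
1%; the 20% post-yield slope is an arbitrary documented choice used only for
recovery testing), `gen_block_fixture()` (rectangular block with the
closed-form plane-strain uniaxial record), and `gen_stress_tensors()`
(random plane-strain-compatible tensors with dense-eigensolver oracle
values). Generators are deterministic given their seed and do not disturb
the caller's RNG stream. These fixtures emulate the statistical structure of
instrument recordings, not instrument artifacts (no piezo hysteresis,
thermal drift, or cantilever tilt), so passing recovery tests demonstrate
estimator correctness under the stated noise model, not robustness to every
real-world pathology.

## Problem sizes and runtimes

The default mesh (target edge 0.9 mm) has roughly 5,000 quadratic triangles
(about 11,000 nodes); the refinement check doubles the resolution to about
21,000 triangles. Variant comparisons in the tests run at 0.3 MPa (one load
step) and 1.2 MPa (four steps); a solve takes seconds to a couple of
minutes on one core. Parameter-recovery studies use 100 synthetic force
curves and 200 load-deformation records.

## Known limitations

* Quasi-static, single-phase elasticity: no poroelastic fluid flow,
  viscoelasticity, or rate effects, although growth cartilage has all three.
* The 2D plane-strain idealisation exaggerates compliance relative to an
  axisymmetric or 3D epiphysis.
* The Saint Venant-Kirchhoff law is non-polyconvex and caps transmissible
  compressive stress (see the limit-point discussion above); conclusions at
  nominally higher loads rest on the trends established below the limit.
* Geometry is a parametric idealisation, not segmented anatomy; subdomain
  shapes beyond the printed outer dimensions are reconstructions.
* Hertz fitting assumes a rigid spherical indenter on an elastic half-space;
  thin samples and adhesive contact violate it in known directions.
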