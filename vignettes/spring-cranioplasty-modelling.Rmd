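---
title: "Modelling spring-assisted cranioplasty from head-surface scans"
author: "SpringCranio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spring-assisted cranioplasty from head-surface scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpringCranio)
```

## The clinical problem

Sagittal craniosynostosis fuses the sagittal suture of an infant skull
prematurely; growth perpendicular to the suture stops and the head becomes
long and narrow (scaphocephaly, cephalic index CI = BPD/OFD well below
normal). Spring-assisted cranioplasty (SAC) corrects this with two
parasagittal osteotomies and two pre-crimped metallic spring distractors
(models S10/S12/S14: identical geometry, 60 mm nominal fully-open length,
wire diameters 1.0/1.2/1.4 mm and correspondingly increasing stiffness)
that push the parietal bone flaps apart over days.

Finite-element prediction of spring expansion conventionally starts from a
CT scan. Most SAC candidates never receive one, so this package builds the
simulation model from a radiation-free 3D stereophotogrammetry surface scan
instead. The price is that everything under the skin must be supplied by
population knowledge: scalp thickness, skull thickness, and where the
(invisible) coronal and lambdoid sutures run.

## The S-model construction

`buildSModel()` runs the surface-scan ("S model") recipe:

1. **Base plane.** The plane through the nasion and both tragions
   (`fitBasePlane()`). The head surface is cut along it.
2. **Skull estimate.** The cut surface is offset inward along angle-weighted
   vertex normals by the population-average scalp thickness
   (`offsetInward()`). The population default is 2.8 mm (sd 0.4 mm), as
   measured on SAC cohorts; skull thickness, used as the homogeneous shell
   thickness later, is 2.5 mm (sd 0.4 mm).
3. **Anatomical frame.** A and P are the extreme points of the base-plane
   section along its long principal axis; the midline plane contains AP and
   the base-plane normal.
4. **Suture planes.** The coronal plane crosses AP at
   B = A + abFrac (P - A), perpendicular to the midline plane, tilted so its
   cranial-going trace makes the coronal angle (default 83 degrees, sd 4)
   with the ray B->A; the lambdoid plane does the same at
   L = P - lpFrac (P - A) with the lambdoid angle (default 68 degrees,
   sd 3) against L->P. Foot ratios default to abFrac = 0.30 and
   lpFrac = 0.25. The point-angle definition (angle A-B-Bregma at B) and
   this plane parametrisation agree exactly whenever bregma lies on the
   plane, which is how the phantom generator places it; the duality is
   tested both ways.
5. **Five regions.** The shell is split into frontal bone, coronal suture,
   parietal bone, lambdoid suture and occipital bone. Suture bands are
   2 mm wide; the shell is first *geometrically* split along the band-edge
   planes so the bands are exact strips rather than rows of whole
   triangles, and the band width is verified as band area divided by the
   length of the suture mid-curve.
6. **Osteotomies and notches.** Two parasagittal slots are carved through
   the parietal region and four notch vertex sets are marked on the lateral
   slot edges. The published figures show this geometry but do not
   dimension it, so the `OsteotomySpec` defaults (lateral offset 25 mm,
   kerf 1 mm, AP extent 0.34-0.76, notches at 0.25/0.75 of the cut) are
   package choices, surfaced in the run configuration and documented as
   non-measured.

A CT-derived outer skull surface can be ingested instead
(`ingestCTModel()`): it skips the offset, applies a user-supplied uniform
growth rescale, and, when bregma/lambda are available, orients each suture
plane through its measured landmark (with the foot still placed by the
population ratio; a single landmark cannot determine both).

### Measurement operators

Tissue thickness is *unsigned nearest-point surface distance*
(point-to-triangle), not a normal-ray intersection: rays are fragile on
noisy scans, and nearest-point distance is what common surface-comparison
tooling computes. Measurements exclude everything below 25% of the skull
height above the base plane (`cropPlaneAtFraction()`), keeping orbits and
skull base out of the averages. BPD and OFD are maximal extents of the
supra-base-plane surface perpendicular to the midline and along AP - the
deterministic cephalometric convention; clinical practice does not fix
the measurement planes, so extents were chosen and are used consistently
for PREOP, POSTOP and FU. Rank correlation between model
series (`spearmanRho()`) reports the exact permutation p-value by full
enumeration of all n! rank permutations for n <= 9 without ties, and the
t-approximation otherwise.

## The expansion simulation

`femAssemble()` + `solveQuasistatic()` implement a quasi-static,
geometrically nonlinear shell model with 3 translational degrees of freedom
per node:

* **Membrane**: St. Venant-Kirchhoff plane-stress triangles (exact large
  rotation behaviour, analytic gradients, element Hessians by central
  differences of the gradient).
* **Bending**: discrete-shells hinge energy `k_e (theta - theta0)^2` on
  every interior edge, with
  `k_e = D / (2 c) * 3 |e|^2 / (2 (A1 + A2))`,
  `D = E h^3 / (12 (1 - nu^2))`. The constant `c = 1.43` was calibrated
  once against the closed-form bending energy of a cylindrically bent
  plate on near-equilateral meshes (direction spread below 2%); with it,
  a clamped square plate under a centre point load reproduces the
  Kirchhoff series deflection within a few percent at ~2k elements, which
  is the test shipped with the package.
* **Clamped edges**: boundary edges whose nodes are fixed receive *ghost
  hinges* - the rest-state mirror of the adjacent triangle, held fixed -
  so the clamped skull base resists rotation as a clamped shell edge
  should. The base rim is detected as the open boundary loop lowest above
  the base plane and is fully constrained, mimicking the tethering of the
  skull base.
* **Springs**: linear push-only force elements,
  `F = k (60 - opening)` clamped at zero, attached at the centroid
  vertices of the anterior and posterior notch pairs across the midline.
  The simulation starts from the geometry as carved: the initial opening
  is the distance between the attachment nodes (~51 mm on the default
  phantom). A spring crimped to ~25 mm for insertion expands freely until
  its footplates contact the notches, so the crimped length is device
  state, not a mechanical input; what loads the skull is the force at the
  geometric opening. The spring load is ramped linearly over the first
  second of pseudo-time to aid convergence; the POSTOP snapshot at t = 1 s
  therefore carries the full load and, with relaxation times of hours, is
  effectively the instantaneous elastic response.
* **Viscoelasticity**: a Prony relaxation series applied to the elastic
  internal-force vector of each material group (quasi-linear hereditary
  integral). The state update uses the exact exponential recurrence for
  piecewise-linear force histories, and the Newton tangent is the elastic
  tangent scaled by the per-step increment factor
  `(1 - sum g_i) + sum g_i (tau_i/dt)(1 - exp(-dt/tau_i))`. Two limits are
  tested: the t = 1 s response equals the elastic solution, and the 5-day
  opening matches an elastic solve with the long-term modulus
  `E (1 - sum g_i)` within 2%.
* **Solver**: full Newton with backtracking line search on the residual
  norm, sparse Cholesky (with diagonal-shift fallback for indefinite
  tangents), convergence at residual below `1e-6 x` the applied spring
  force. Global force balance at the clamped nodes is recorded at every
  step.

The time grid is logarithmic from 1 s to 5 days (432000 s; default 40
points after a 5-step ramp) because creep spans five orders of magnitude in
time. Openings are recorded at every grid point and are monotone
non-decreasing - asserted on every run.

### Material and spring constants are configuration

Published SAC models take their elastic/viscoelastic properties from
prior calibration studies; no standard constants exist. The defaults
shipped here -
skull E = 421 MPa, nu = 0.22; suture E = 8 MPa, nu = 0.45; single-term
Prony g1 = 0.5, tau1 = 3e4 s for both; spring stiffnesses 0.25/0.52/0.96
N/mm scaling as wire diameter to the fourth power - are explicit
placeholders with anatomically plausible orders of magnitude. Every
acceptance-style check in the package is self-consistent under these
values, but users predicting real surgeries must substitute calibrated
constants via the run configuration. Contact between bone flaps, brain
loading, and post-operative skull growth are not modelled (the latter is a
stated limitation of this class of models).

## Synthetic study conditions

No patient scans can ship with the package, so `generateHead()` emulates
the cohort geometry analytically: a superellipsoid with OFD 125 mm, BPD
96 mm (CI 0.768, moderate scaphocephaly), 80 mm height above the base
plane, its widest section placed 20% of the height above the base plane so
that the biparietal maximum lies on the mobile parietal flaps rather than
on the clamped rim. Landmarks are analytic: nasion/tragions exactly on the
base plane, bregma and lambda where the configured suture planes meet the
midline surface - which is what makes the construction/measurement
round-trip a genuine identity test. `generateTwoLayer()` stacks exact
inward offsets (skin 2.8 mm, skull 2.5 mm by construction), and
`generatePopulation()` draws phantom parameters from normal distributions
centred on the published cohort averages (2.8 +/- 0.4 mm, 2.5 +/- 0.4 mm,
83 +/- 4 deg, 68 +/- 3 deg; spreads without published values are package
choices).

What passing on phantoms does *not* show: real scans have noise, ears,
faces, asymmetry and non-planar sutures; the phantoms are smooth, convex
and symmetric. The parameter-recovery results demonstrate correctness of
the operators, not clinical accuracy of the defaults. Cohort-level
validation - comparing predicted spring openings against intra-operative
and radiographic measurements - requires patient scans and lies outside
what any synthetic phantom can demonstrate.

## Numerical choices and problem sizes

Geometric coincidence tolerance is 1e-6 mm; sliver faces below 1e-10 mm^2
are dropped after plane splits; bowtie (pinch) vertices created by
box-shaped face removal are split. The default phantom resolution (3 mm
target edge) yields roughly 9-10k shell elements, matching the mesh
density class reported for surface-scan models in this application; the
test suite uses 6-8 mm phantoms (1-3k elements) for speed, and the
mesh-consistency test verifies that openings change by less than 2%
between successive refinements. The full 5-day solve at default resolution
takes a few minutes on one CPU.

## Known limitations

* Hinge bending is calibrated for cylindrical modes; doubly-curved bending
  carries a few percent model error (visible as the plate benchmark's
  offset from the Kirchhoff constant).
* The quasi-linear viscoelastic treatment relaxes the internal force
  functional, not the stress tensor; for the small-strain, rotation-
  dominated kinematics of spring expansion the difference is negligible,
  and the relaxed-modulus limit is exact by construction.
* Osteotomy geometry and material constants are configuration defaults,
  not measurements.
* No flap contact, no intracranial pressure, no post-operative growth.
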