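---
title: "Patient-specific finite-element comparison of tibial extension stems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific finite-element comparison of tibial extension stems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After total knee arthroplasty (TKA), the tibial baseplate can be augmented
with an intramedullary extension stem. Stems stabilise the construct, but a
stiff metallic rod inside the tibia changes how load travels to bone:
proximal bone under the tray is partially bypassed (stress shielding, a
driver of long-term resorption) while the bone around the stem — in
particular near its tip — is loaded harder, raising the local fracture
risk. Which stem length and diameter best balances these effects is a
biomechanical question that finite-element (FE) models built from a
patient's CT scan can address before surgery.

`stemfea` implements that modelling chain end to end: a CT-like volume with
known ground truth, virtual surgery, conformal quadratic tetrahedral
meshing, CT-based heterogeneous material mapping, a linear-elastic solve
under physiological compressive load cases, and fracture-risk
post-processing, organised as a six-configuration comparative study
(a stemless tray and five stems: 20/45/70 mm long, 9/12.5/14 mm wide).

## The synthetic phantom and what it stands for

Patient CT data cannot be redistributed, so the pipeline ships a synthetic
proximal-tibia phantom with analytic ground truth. The phantom is a loft of
superelliptical cross-sections along the shaft axis: a circular diaphysis
(outer radius 13 mm) flaring over the proximal 40% of its 110 mm length
into a 72 x 48 mm plateau with a boxier cross-section. Tissue structure
follows long-bone anatomy:

* a cortical shell (1.85 g/cm^3) that is thick distally (4.5 mm) and thins
  toward the plateau (1.5 mm);
* metaphyseal/epiphyseal trabecular bone with a smooth radial density
  gradient, 0.25 g/cm^3 on the axis to 0.60 g/cm^3 at the endosteal
  boundary;
* a medullary canal: below 55% of the bone length the interior is marrow
  (0.08 g/cm^3 bone-equivalent density), blending into trabecular bone over
  the next 25% through a C1 smoothstep. The canal matters: the
  stem-tip strain concentrations that drive the comparative findings arise
  where the stem ends inside this compliant region, and a phantom without a
  canal suppresses them entirely.

The volume is rasterized at the reference CT spacing
(0.449 x 0.449 x 0.499 mm) by inverting the density calibration at each
voxel centre; air outside the bone is exactly -1000 HU, and optional
Gaussian HU noise (truncated at 4 SD, seeded) can be added to tissue
voxels. Because the calibration is applied in reverse at generation time,
density mapping can be tested against exact ground truth — constant and
affine fields are recovered to 1e-9, smooth fields to better than 1% of a
dense Monte-Carlo per-element oracle.

What the phantom does **not** emulate: trabecular microarchitecture,
cortical porosity, beam-hardening or partial-volume artefacts of real CT
reconstruction, inter-patient anatomical variation, and the subchondral
density structure of an osteoarthritic plateau. Passing tests on the
phantom therefore validate the *pipeline machinery* and the *direction* of
biomechanical effects, not patient-specific absolute magnitudes.

## Virtual surgery

The plateau is resected 2 mm below its apex with a 3 degree joint-line
obliquity (coronal tilt); the cut is an exact half-space clip of the lofted
surface, capped and audited for closedness. The implant is parametric
(the commercial tray's CAD is proprietary): a superelliptical tray,
a coaxial cylindrical stem with a short distal taper, and four radial fins
on a central boss, all dimensions exposed in configuration. The tray
footprint default (60 x 40 mm) is the largest that covers the resection
face without protruding (coverage 0.82), following the surgical rule of
maximising plateau coverage; the stemless model is a bare tray, so its
axial extent equals the tray thickness exactly. The implant is placed with
the tray flush on the oblique cut (its axis therefore tilts 3 degrees from
the shaft axis — a flat-bottomed tray cannot seat flush otherwise) and the
cavity is carved as an implicit boolean difference, which makes the cavity
conform to the implant surface by construction.

## Meshing and the bonded interface

Meshing uses a structured background grid: each cubic cell is split into
six positively oriented tetrahedra (Kuhn subdivision, conformal across
cells), tetrahedra are classified bone/implant by centroid membership, and
corner tetrahedra are promoted to 10-node quadratic elements (TET10) with
shared midside nodes. Two consequences deserve emphasis:

* **Bonded contact by conformity.** Bone and implant elements come from
  the same grid, so they share interface nodes exactly — the bonded
  (osseointegrated, secondary-stability) condition requires no constraint
  machinery. A dedicated test confirms that re-labelling the same element
  set as one homogeneous body changes the solution by nothing.
* **Staircase boundaries.** Surfaces are resolved to the element size, so
  boundary elements are partial-volume and re-entrant grid corners carry
  artificial stress concentrations. The reported maxima handle this in two
  documented ways (below); a graded, body-fitted mesh in the style of
  commercial pre-processors is out of scope for this package, and the
  mesh is uniform at `global_size` (the contact-zone size setting is kept
  for the region-of-interest definition).

Elements that end up face-disconnected from the main body (classification
islands, or vertex/edge-only contacts that would be zero-energy
mechanisms) are dropped; the audit checks 10 distinct nodes per element,
positive corner Jacobians, no orphan nodes, and disjoint load patches.

Node and element sets: `distal_fixed` (nodes on the distal plane),
`medial_patch`/`lateral_patch` (upward-facing exterior tray faces split by
the sagittal midplane through the implant axis; +x is medial),
`interface` (nodes shared by bone and implant elements), and
`refined_roi` — elements whose centroid lies within `roi_offset`
(default 3 mm) of the interface, this package's rendering of the
"refined contact zone" in which micro-strain percentiles are evaluated.

## Materials

Densities come from Gaussian quadrature of the calibrated HU field over
each bone element (4-point tetrahedral rule by default; the rule
integrates the affine-geometry TET10 elements' degree-2 integrands
exactly), floored at 0.05 g/cm^3. Density maps to Young's modulus through
two power laws (MPa with density in g/cm^3): cortical
`E = 3890 rho^2.39` and cancellous `E = 6570 rho^1.37`, with nu = 0.3 for
all bone. The tissue threshold is the density at which the two laws
intersect, `(6570/3890)^(1/1.02) = 1.6717 g/cm^3` — the conventional
1.68 g/cm^3 split, computed rather than stored so that threshold
classification and "whichever law gives the larger modulus" agree exactly.
A modulus floor of 10 MPa keeps marrow elements from degenerating. The
tray and stem are cobalt-chrome-molybdenum: E = 220 GPa, nu = 0.3.
Moduli are element-constant (quadrature-averaged), matching the
integrate-over-each-element protocol; per-point assignment is a
configuration away but not default.

## Loads, constraints, solver

The distal plane is fully fixed. Each load case applies axial compression
along the mechanical (shaft) axis as a uniform downward pressure per unit
projected area on the tray's superior face, split 60% medial / 40%
lateral and converted to consistent nodal forces of the quadratic face
functions; the per-patch nodal sums are renormalised so each patch carries
exactly its share. Reference cases: walking single-leg support 3 BW
(2250 N), sit-to-stand/stairs 5 BW (3750 N), running 12 BW (9000 N), at
750 N body weight. The sparse symmetric stiffness (4-point Gauss,
assembled in compiled code in blocks to bound peak memory) is solved by
supernodal Cholesky after eliminating fixed dofs; the free-dof residual
must fall below 1e-8 and reactions are checked against global
equilibrium. Because the model is linear, one unit-load solve per
configuration is scaled exactly to the three load cases (an audit flag
forces independent solves; the two paths agree to solver precision, and
every reported quantity is exactly load-linear — the 12 BW row is four
times the 3 BW row).

## Outputs and the fracture-risk statistic

Strains are recovered from shape-function gradients at the Gauss points
and volume-averaged per element; stresses follow by Hooke's law. Reported
per configuration and load case:

* maximum von Mises stress, maximum equivalent elastic strain (von
  Mises-type invariant with the customary 1/(1+nu) factor; switchable to
  von Mises stress over E, identical in uniaxial states), and maximum
  fracture risk `RF = 100 x |principal strain|_max / 0.00728`, where the
  ultimate strain is recomputed as 70% of the 0.0104 compressive strain
  capacity of bone (the conventional rounded value is 0.0073). RF uses
  the largest *absolute* principal strain — the limit derives from
  compressive capacity and the loading is compressive; the signed
  alternative is an option.
* median and 90th-percentile minimum principal micro-strain over the
  bone elements of the refined ROI (linear-interpolation quantile
  estimator on magnitudes, reported as negative values).
* mean |minimum principal strain| in bone within 5 mm under the tray —
  the quantity in which proximal stress shielding is visible.

Two documented exclusions apply to the maxima only (percentiles and band
means keep all bone-region elements): a 6 mm St-Venant margin above the
fixed distal plane (the truncation boundary is artificially singular),
and a structural-bone filter (mapped density at least 0.2 g/cm^3) —
a strain extremum inside medullary marrow is not a bone-fracture signal,
and marrow elements pinned at the modulus floor diverge under refinement
at re-entrant implant corners.

## Numerical choices and degenerate inputs

Half-space clipping splits straddling triangles exactly and fans the cut
polygon about its centroid (valid for the star-shaped sections all solids
here produce). Surface audits distinguish *closed* (every directed edge
balanced by its reverse — the property that the surface bounds a solid)
from *manifold* (every edge shared by exactly two faces): lofted and
clipped surfaces are both; voxelized boundaries are closed but may pinch
along grid edges. Out-of-volume HU samples return air (-1000) and are
counted, since cut planes may graze the volume border. Zero-slope
calibrations, non-positive phantom dimensions, resections that miss the
bone, off-catalog stems (warning only — the catalog is configuration),
empty node sets, and rank-deficient constraint sets all fail loudly with
the offending field named.

## The convergence protocol and its desk-scale limits

The convergence driver re-meshes one configuration at a descending ladder
of element sizes on a half-scale phantom (a 55 mm version of the same
shape family with a proportionally scaled implant), solves the walking
case, and accepts the first size at which every monitored output — max
stress, max equivalent strain, max fracture risk over structural bone —
changes by less than 5%. The shipped ladder is {3, 2, 1.5} mm: the next
conventional rung would put the direct solver's fill-in beyond an 8 GiB
workstation for this geometry (about 340k dof under an AMD ordering).
On this ladder the stress maximum settles (0.4%, then 5.0%) while the
strain and fracture-risk maxima still oscillate around 20% between rungs:
point maxima of a heterogeneous field on *staircase* meshes keep flipping
between partial-volume boundary elements, and do not meet the 5% rule at
any size this package can afford. The convergence table is reported as-is
(`analysis/03_convergence.R`); treating the mesh as converged for point
maxima would overstate what the uniform background-grid mesher delivers,
and the corresponding acceptance test is expected to flag exactly this.

## Study design and problem sizes

`run_study()` executes the six configurations under the three load cases
(18 summary rows) on the default phantom at the `coarse_preset()` element
size of 3 mm — about 20k TET10 elements and 95k dof per model, roughly
2.5 minutes and under 3 GiB for the full study on one CPU. These sizes
are the package's desk-scale operating point: fine enough that the
comparative directions are stable (the same directions hold at 2.5 mm),
coarse enough to iterate with. The driver scripts under `analysis/`
run the phantom build, virtual surgery, convergence ladder, the study,
and the stem-versus-stemless comparison in order, writing tables under
`results/`.

## What the phantom study reproduces — and what it does not

With a stem of any catalog size, the mean compressive strain in bone
directly under the tray drops by 35-50% relative to the stemless tray, in
every load case — the proximal stress shielding that motivates cautious
stem use. The compressive micro-strain tail (ROI p90) rises with the
9 mm stems and the 45 x 12.5 mm stem, as in the reference comparative
pattern. It does *not* rise for the 14 mm stem and is a statistical tie
for the 70 mm stem on this phantom: with a bonded interface inside a
generic elderly medullary canal (endosteal radius 8.5 mm), a 14 mm stem
remains separated from the cortex by a compliant marrow annulus and
spreads load over its large lateral surface, so the tip concentration
that press-fit cortical contact produces in vivo is suppressed. Capturing
that mechanism would require frictional contact and patient-specific
canal fit, both outside this package's scope (the interface here models
secondary, osseointegrated stability). The stemless model shows the
lowest fracture-risk maximum, and von Mises stress maxima differ little
between configurations, consistent with the reference pattern.

## Known limitations

* Uniform structured meshes; no graded refinement, no body-fitted
  surfaces. Point maxima inherit staircase noise (see above).
* Linear elasticity, bonded interfaces, axial loading only: no
  micromotion, no friction, no shear/torque components, no varus/valgus
  malalignment, no posterior slope variation.
* One synthetic anatomy; absolute magnitudes are not patient
  predictions.
* The density-modulus laws are the two reference power laws; alternative
  site-specific laws are configuration, and a systematic modulus
  sensitivity sweep is supported only as a configuration exercise.
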