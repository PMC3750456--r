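---
title: "Quantifying the quality of orbital reconstruction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the quality of orbital reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(orbitqc)
```

## The clinical question

After a blow-out fracture of the orbit, the bony cavity that houses the
eyeball is enlarged; if the surgeon's titanium-mesh reconstruction does not
restore the original volume and wall shape, the patient risks enophthalmos
(a sunken eye) and hypoglobus. Two complementary quantities describe how
"true to original" a reconstruction is:

1. **Volumetry** — the volume of the bony orbital cavity, measured on the
   pre-operative CT (unaffected and fractured side) and on the
   post-operative cone-beam CT (CBCT), in ml.
2. **Shape deviation** — assuming facial symmetry, the unaffected orbit
   mirrored across the midsagittal plane is the ideal target shape; the
   signed minimal perpendicular distance between this mirror template and
   the reconstructed wall, summarised over a nine-region partition of the
   orbital walls, quantifies local reconstruction error in mm.

`orbitqc` implements both measurements as a reproducible pipeline and, since
no clinical images travel with the package, ships a synthetic phantom
generator whose ground truth exercises every stage.

## Volumetry

### Segmentation model

The bony orbit has no closed algorithmic definition in the clinical
workflow — it is marked slice by slice by an operator and bounded anteriorly
by the line through the lateral (L) and medial (M) orbital rim points. The
package turns this into a reproducible procedure:

* **Bone thresholding.** Voxels at or above `bone_threshold` are bone.
  The default (300, HU-like) suits CT; CBCT intensities are uncalibrated,
  so the post-operative threshold is an explicit, modality-specific
  configuration value with no universal default.
* **Morphological closing** of the bone mask with a ball of radius
  `closing_radius_mm` bridges fracture defects. A gap of width *g* is
  reliably sealed once the closing radius reaches *g* (voxelisation and the
  obliquity of fracture lines make radii between *g*/2 and *g* marginal);
  the phantom's default 2 mm fracture lines are handled with a 2 mm
  closing.
* **Seeded 6-connected flood fill** of non-bone voxels from a point inside
  the cavity (derived from the landmarks: midway between the rim centre and
  the apex). The fill is additionally bounded by the anterior rim plane —
  the plane through L and M swept along the slice axis — because the orbit
  opens anteriorly into the face: without that bound, any fill would escape
  through the orbital aperture, exactly as a manual marking that never drew
  the anterior border would. A `max_volume_ml` guard (default 50 ml, about
  twice a normal orbit) converts a fill that escaped through an unbridged
  wall defect into a hard "leak" error telling the caller to raise the
  closing radius, rather than a silently absurd volume.
* **Anterior clipping** then removes voxel centres at or anterior to the
  rim plane, and the volume is the exact voxel count times the cell
  volume, reported in ml. A voxel is modelled as a cell of size `spacing`
  centred at `origin + index * spacing`; this makes volume = count x cell
  volume an identity rather than an approximation, which is what the
  volumetry oracle tests assert.

Slice thickness above 1 mm triggers a warning: orbital volumetry at the
sub-ml level needs sub-millimetre sampling.

### Why a stop plane instead of "not yet clipped"?

The flood fill and the anterior clip use the same L–M rim plane. The fill
is blocked at the plane (otherwise it cannot terminate); the clip is still
applied afterwards and owns the exact boundary rule (centres strictly
posterior of the plane are kept). The two stages stay separate so that the
clip can also be applied to masks segmented by other means.

## Mirror template and ROI-restricted registration

The unaffected cavity surface is extracted with marching tetrahedra over
the voxel-centre grid (six-tetrahedra Kuhn subdivision, consistent across
cells, hence watertight) after a small Gaussian smoothing of the binary
indicator (sigma = 1 voxel by default). The smoothing suppresses the voxel
staircase: on a 10 mm sphere at 0.5 mm voxels the extracted surface is
within about 0.04 mm RMS of the true sphere and its enclosed volume within
2% of the analytic value. Surfaces are oriented outward; the divergence
theorem volume is therefore positive and comparable to the voxel count.

The midsagittal plane is the total-least-squares plane through at least
three midline landmarks. Mirroring is an exact reflection with the face
winding flipped so orientation survives. Because the template is the
patient's own mirrored anatomy, registration onto the reconstructed side is
**rigid only** — no scaling, no deformation.

Registration is trimmed point-to-plane ICP, initialised by a closed-form
(Kabsch) fit of the mirrored L/M/apex landmarks onto the affected side's.
Defaults: 100 iterations maximum, convergence at 1e-4 mm change of the mean
correspondence distance, 10% worst-pair trimming, 5 mm correspondence cap,
and a deterministic stride subsample of at most 5000 ROI vertices — there
is no randomised sampling anywhere, so identical inputs give bit-identical
transforms. Nearest-triangle queries use a uniform grid with an exact
shell-distance bound and break exact ties toward the smallest triangle
index.

The ROI is the point of the method: only the orbital roof and other
unaffected wall regions participate in the matching, with the reconstructed
wall, the rim band and unassigned vertices excluded. If the deformed wall
were included, the optimiser would split the reconstruction error between
the pose and the deviation map and bias the measurement toward zero; the
registration tests inject a known floor deformation and verify that with
the floor excluded the measured amplitude stays within 10% of truth while
an unrestricted, untrimmed fit visibly absorbs part of it.

## Deviation mapping

For every template vertex the closest point on the reconstructed surface is
found (vertex, edge and face-interior candidates all considered) and the
distance signed by the target's angle-weighted pseudonormal at the foot
point (Baerentzen–Aanaes), so the sign is well defined on edges and
vertices too. Convention: **positive = the reconstructed wall lies outside
the template cavity** (toward bone — local enlargement), negative = inside
(toward the globe). Vertices with no correspondence within
`max_correspondence_mm` (default 10 mm) are flagged missing and excluded
from all moments, never silently zeroed.

Color coding follows the clinical reading: green at zero, red at +1.5 mm,
blue at -1.5 mm, linear in between, saturated beyond; missing vertices are
grey. The 1.5 mm clamp is the scale on which residual wall deviations are
clinically judged; it is configurable.

Per-region summaries report the signed mean, SD, maximum absolute deviation
and a **peak** estimate defined as the 99th percentile of the absolute
deviation. The percentile rather than the raw maximum is used to recover
deformation amplitudes: both surfaces are isosurface extractions whose
worst single-vertex staircase error can exceed the ±0.15 mm amplitude
tolerance, while the 99th percentile over a few thousand region vertices is
robust to those isolated outliers yet still sits at the top of a smooth,
broad bump.

## The nine-region partition

The walls are classified geometrically around the orbital axis (rim centre
to apex): in the plane orthogonal to the axis, each vertex's radial
direction is compared with four cardinal directions — inferior (floor),
superior (roof), toward the midsagittal plane (medial wall) and away from
it (lateral wall) — with 45 degree sectors by default (configurable
half-angles). The roof is kept separate because it serves as registration
ROI, not as a reconstruction target. Vertices within 1.5 mm behind the rim
plane are labeled `rim`; anything anterior is `unassigned`. Each wall is
then cut into anterior/central/posterior thirds of the normalised depth
(signed distance behind the rim plane divided by the apex depth), with
right-closed boundaries: a vertex exactly at 1/3 is central. "Thirds" is
read as equal thirds of orbital depth — the natural geometric reading of an
anterior/central/posterior subdivision.

The medial-wall-to-floor transition zone, clinically the most demanding
area, is additionally reported as the band of wall vertices within 2 mm of
the medial/floor sector boundary; it is an extra output and does not
disturb the partition.

Implant coverage: titanium is far denser than bone, so implant voxels are
thresholded (phantom model: bone 1200, implant 3000, threshold 2000 —
clinical CBCT values are configuration), kept as connected components of at
least 20 voxels, and projected onto the template: a vertex counts as
covered when it lies within `projection_distance_mm` (default 2 mm — the
sheet sits on or just behind the wall) of an implant voxel, and each
region's coverage is the covered fraction of its Voronoi-weighted vertex
area.

## The phantom generator

The generator emulates the study conditions rather than realistic anatomy:

* **Geometry.** Each orbital cavity is a half-ellipsoid opening anteriorly
  at a flat rim plane, wrapped in a 2.5 mm bone shell, inside a homogeneous
  soft-tissue block. The default semi-axes are triaxial (ratios 1 : 1.25 :
  0.9, width : depth : height) and scaled so the clipped cavity volume is
  exactly 26.6 ml analytically ((2/3) pi a b c) — the mean male unaffected
  orbital volume; an `asymmetry` factor scales the contralateral side.
  The voxel grid aligns cell faces with the rim and mirror planes, so the
  clip introduces no half-cell quantisation and measured volumes are stable
  to better than 0.1% between 1 mm and 0.5 mm grids.
* **Fracture.** A blow-out is modelled as an outward radial bulge of the
  cavity boundary (angular Gaussian around a wall/region-specific
  direction, sigma 25 degrees) with the bone shell following the displaced
  boundary — a displaced fragment, not a hole. The bulge amplitude is
  calibrated by numerical integration (and checked against voxel-count
  truth) to add a requested volume, 3.4 ml by default — the largest
  posterior-ledge enlargement reported clinically; an unattainable request
  errors with the attainable maximum. The fragment is separated from the
  shell by fracture lines of width `defect_gap_mm` (default 2 mm) that
  spare the rim, as hinged "trapdoor" fragments do; a fill without closing
  escapes through them (the leak test), while closing at the gap width
  seals them.
* **Reconstruction.** The reconstructed state restores the ideal wall with
  a residual angular-Gaussian deviation (default +1.5 mm at the anterior
  floor, sigma 18 degrees) and an optional 1 mm thick high-intensity sheet
  lining the reconstructed area — the titanium mesh.
* **Modalities.** CT: intensity scale 1.0, additive Gaussian noise sigma
  15; CBCT: scale 0.8 and sigma 40, reflecting lower dose and uncalibrated
  intensities qualitatively. All noise flows through one seed; given the
  seed, every output is bit-reproducible.
* **Cohort generator.** Case records draw gender (58:36 male:female),
  treatment group (60:34 navigation:conventional) and fracture class
  (34/20/36/4 — anterior/central floor, posterior ledge, complex medial,
  complex lateral) with the study's composition; unaffected CT volumes are
  gender-specific normals (male 26.6 ± 2.8 ml, female 25.2 ± 2.6 ml), CBCT
  repeats CT with 0.4 ml measurement noise, fracture enlargement is
  class-dependent, and the post-operative residual is 0.0 ± 0.5 ml for the
  navigation group versus 0.3 ± 0.5 ml conventional — choices that encode
  "navigation restores the unaffected volume; conventional leaves a small
  residual".

What the phantom deliberately does **not** model: real orbital shape
(nasolacrimal fossa, concave anterior floor), beam hardening and metal
artefacts, soft-tissue contrast, or operator variability in landmark
picking. Tests passing on phantoms therefore validate the algorithmic
chain — segmentation, mirroring, registration, mapping, statistics — not
the clinical difficulty of thresholding real CBCT or picking rim points on
real anatomy.

## Statistics

Volume comparisons are paired and two-sided: t-test by default, Wilcoxon
signed-rank as an alternative; zero-variance differences are reported as
degenerate with p = 1 instead of erroring. CT-vs-CBCT agreement adds
Bland-Altman mean difference and 1.96 SD limits. No multiple-testing
correction is applied by default, matching the original analysis practice;
`p.adjust` can always be applied downstream. Calibration tests hold the
paired t-test to its nominal 5% level (±2% over 1000 null simulations) and
to >99% power for a 2 ml shift at n = 30, sigma = 1 ml.

## Numerical choices and edge cases

* Marching tetrahedra interpolate the 0.5 level; degenerate (zero-area)
  triangles are dropped at 1e-12 mm² and unreferenced vertices pruned.
* Exact closest-point ties are broken toward the smallest triangle index,
  making the deviation map deterministic.
* Rigid transforms are validated at construction (orthonormality and
  det = +1 to 1e-9); planes carry unit normals to 1e-12.
* STL read welds bit-identical vertex triples (exact hash), so triangle
  soup becomes an indexed mesh; geometry round-trips at 1e-6 mm through
  ASCII formats.
* The pipeline caches each stage keyed by a hash of the analysis-relevant
  configuration (output paths excluded), so interrupted runs resume and
  reruns are bit-identical; every tabular output carries the hash.
* Problem sizes used in the shipped tests: 0.5 mm phantoms
  (~230 x 80 x 154 voxels) for the volumetric and deviation checks, 1 mm
  phantoms for pipeline-level tests, icospheres at ~0.5 mm edge length for
  the analytic distance checks, and 500–1000 replicate simulations for the
  statistical calibration.

## Known limitations

* Wall/third boundaries are geometric conventions (45 degree sectors,
  equal depth thirds); anatomically guided boundaries would need an atlas.
* CBCT thresholds must be supplied per scanner; nothing is auto-calibrated.
* The rigid-only registration cannot represent a template that is itself
  deformed (e.g. bilateral trauma violating the symmetry assumption).
* Voxel-count volumetry has no partial-volume weighting; at 0.5 mm voxels
  the discretisation error on a 26.6 ml orbit is well under 1%, but coarse
  anisotropic scans will do worse.
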