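---
title: "Methods: surgical-planning morphometry on breast MRI label maps"
author: "mammoplan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surgical-planning morphometry on breast MRI label maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mammoplan)
```

This vignette records how `mammoplan`'s procedures are defined, which
parameters matter, the numerical conventions behind them, and what the
digital phantom does and does not establish about real data.

# Data model and coordinate conventions

A `LabelMap` is a 3D integer array with positive voxel spacing (mm) and a
`TissueSchema` mapping the seven semantic classes (air, skin, adipose,
fibroglandular, vessel, chest, tumor) to integer labels. All analysis
assumes one fixed anatomical frame, LPS-like: axis i runs patient-right to
patient-left, axis j anterior to posterior, axis k inferior to superior.
NIfTI input is reconciled to this frame from the affine direction cosines;
only axis permutations and flips are accepted. Oblique acquisitions are
rejected rather than resampled, because every downstream quantity (axis
extents, bounding boxes, quadrant planes) is defined on an axis-aligned
lattice and silent resampling would change measured values.

Voxels are half-open boxes: voxel `(i,j,k)` (1-based) occupies
`[(i-1)s, i s)` per axis, its center sits at `(i-0.5)s`, and its corners lie
exactly on the integer spacing lattice. This convention makes voxel-corner
vertex sets exact, which the distance and hull modules rely on.

Bilateral volumes are split at a mid-sagittal grid plane. Clinical bilateral
MRIs are acquired centered on the sternum, so the default midline is the
center plane `floor(Ni/2)` (0-based); the index is configurable everywhere,
and `midline = 0` treats a unilateral volume as a single left breast. This
was a genuinely open choice: nothing in the source data dictates how to cut
a bilateral volume, and an image-center plane is the simplest rule that is
correct for sternum-centered acquisitions.

# Nipple localization

Candidates are all voxels of one side whose centers lie within
`neighborhoodRadiusMM` (default 8 mm, Euclidean on voxel centers) of the
center of at least one air voxel AND one skin voxel AND one fibroglandular
voxel; the landmark is the unweighted centroid of the candidate centers,
moved `posteriorOffsetMM` (default 6 mm) along +j. Both defaults are the
operating points of the published heuristic. The center of mass is
unweighted and the 8 mm test uses voxel centers; both details were left
open by the original description and are fixed here for determinism. An
empty candidate set raises a `landmark-not-found` error — never a silent
default, since every downstream distance would inherit the fabricated
point.

The heuristic works because fibroglandular (retroareolar/ductal) tissue
approaches the skin only behind the nipple; in breasts where the gland is
everywhere far from the skin the candidate region is empty and the error is
the correct outcome.

# Breast box

Five key points define the initial box: (1) the center of mass of all five
breast tissues; (2) the most anterior skin-surface point on the side's
central sagittal plane, with ties broken by smallest k then smallest i (no
tie rule exists in the source description; any fixed rule serves); (3) a
reference point 6 mm posterior to (2), aligned with (1) medial-laterally;
(4a,b) the skin-surface points nearest the reference in the transverse
projection (2D Euclidean after dropping k), one on each side of the
reference's x, fixing the medial/lateral faces; (5a,b) the same in the
sagittal projection, fixing the inferior/superior faces. The anterior face
is the most anterior skin-surface point of the side; the posterior face is
the most anterior chest voxel within the box footprint. "Skin surface"
means skin voxels with at least one face-neighbour labelled air, which
excludes the interior of the skin shell.

A corrective pass then walks any face that still excludes breast tissue
outward one voxel at a time until nothing is excluded (the inframammary
fold is the classic case: tissue can bulge below the initial inferior key
point). The walk cannot leave the side's subvolume, because the tissue's
tight bounds are inside it; the fallback to a tight bounding box is kept
for robustness and flagged in the result. The posterior face participates
in the corrective pass too, so the invariant "zero breast-tissue voxels
outside the box" holds unconditionally — this is also what makes the box
monotone under tumor growth.

# Tumor metrics and distances

Axis extents are outer-edge spans, `(max index − min index + 1) · s`. With
this reading the longest axis-aligned dimension is the maximum of the three
extents and the bounding-box volume is their product — the only reading
under which "maximum of the per-plane longest dimensions" and "product of
the dimensions" are mutually consistent. In-plane oblique diameters (a
RECIST-style reading) would break the product identity and are out of
scope.

Distances use deduplicated voxel-corner vertex sets (8 corners per voxel)
in mm, and return the minimum Euclidean distance between the tumor's set
and the landmark's set (or a point, for the nipple). Queries run on an
exact KD-tree (`RANN`, ANN backend with zero approximation error) and are
bit-identical to the brute-force pairwise minimum, which the tests assert.
No sub-voxel surface interpolation is attempted; the discretization error
of corner sets against continuous geometry is bounded by one voxel diagonal
and is measured directly against the phantom's analytic truth.

The dominant mass is the largest face-connected (6-connectivity) component,
ties going to the earlier component in column-major raster order; 18- and
26-connectivity are available. Face connectivity is the conservative
default: corner-touching foci remain separate, which is the clinically
meaningful reading for multifocality.

# Quadrant localization

Quadrants are bounded by the transverse plane through the nipple and by the
balance plane, which contains the nipple and the superior–inferior axis and
is rotated about that axis (from the sagittal orientation, range ±45°)
until breast tissue within the box balances to `tol = 0.005` (0.5 % of
total), by bisection of the signed imbalance; if the imbalance does not
change sign over the range, a 0.5° grid scan returns the minimizer,
flagged. The transverse plane is taken to pass through the nipple as well —
the quadrant boundaries are "planes through the nipple", plural. Voxel
counting assigns centers exactly on the balance plane to the medial side
and centers exactly on the transverse plane to the lower side; a center of
mass exactly on a plane names the upper and/or outer quadrant and sets a
tie flag. These tie rules are arbitrary but documented and deterministic.
Outer/inner naming follows laterality (lateral = away from the patient
midline), so mirroring the anatomy preserves quadrant names and negates the
rotation angle.

# Margin hulls

The hull pipeline is: corner-shifted mask → surface extraction → normal
displacement → convex hull.

The corner-shifted mask lives on a grid with one extra voxel per axis and
origin at `−s/2`, so its voxel centers are exactly the corners of the
original tumor voxels. Surface extraction treats the mask values as point
samples at voxel centers and returns the exact boundary of the union of
dual-lattice cells whose eight corner samples are all inside, with vertices
placed exactly at sample positions. For a corner-shifted tumor mask this
reproduces the tumor's voxel-corner envelope: the enclosed volume equals
the voxel volume exactly, the mesh is watertight (every edge shared by two
faces), and a zero-margin hull coincides with the convex hull of the
tumor's corners, so corner containment is exact rather than approximate. A
midpoint-interpolating iso-surface at level 0.5 was considered and
rejected: on a binary corner-shifted field it places the surface half a
voxel outside the corner samples, silently dilating every hull by half a
voxel and breaking the zero-margin volume identity. Masks touching the
image border remain watertight because out-of-range cells count as
outside.

Vertex normals are angle-weighted averages of incident facet normals
(insensitive to how boundary quads are split into triangles). For margin
expansion, a single displaced copy per vertex under-supports the hull at
normal discontinuities: at an envelope corner with normal-cone half-angle
θ the hull boundary falls short of the margin by up to `m(1 − cos(θ/2))`,
which exceeds a voxel diagonal for m = 20 mm. The expansion therefore
replicates each such vertex along graded conic combinations of its
incident facet normals (weights 0–2 per axis, normalized, ~13° angular
resolution). Every copy lies exactly `m` from its vertex, i.e. inside the
true Minkowski offset, so hulls remain conservative under-approximations
of the exact margin expansion while meeting the near-margin bound
`min corner-to-boundary distance ≥ m − one voxel diagonal` at all margins
up to 20 mm. Margins are capped at 20 mm, the maximum the planning use
case calls for.

Multicentric hulls are built per connected component; overlap is tested
pairwise by vertex-in-hull membership against facet half-spaces with
`1e-9` mm slack (the numerical meaning of "lies within" had to be fixed
somewhere; a mm-scale epsilon far below voxel size changes no decisions).
Overlapping hulls merge transitively (union–find) and merged groups are
rebuilt from the union of their members' displaced surface vertex sets —
not from hull vertices only — then testing repeats to a fixed point.
Merging is idempotent, and a fully merged multicentric result equals the
unicentric hull of the same mask.

The convex hull itself is a quickhull with conflict lists implemented in
C++ (no suitable hull was available among the package's dependencies), with
a visibility epsilon of `1e-9` times the cloud diagonal; hull volume comes
from the divergence theorem over outward facets. Degenerate inputs (fewer
than four non-coplanar points) raise errors upstream.

# Evaluation statistics

Dice is `2TP/(2TP+FP+FN)` over voxels; two empty masks score 1.0 with an
explicit `bothEmpty` flag rather than NaN, so callers cannot silently
average an undefined value. Hausdorff uses boundary-voxel centers
(face-neighbour rule, image border counting as outside) in mm — matching a
"boundary pixels" reading rather than a surface-mesh one — and exact
KD-tree queries. Gwet's AC1 is the two-rater, two-category, unweighted
variant; it depends on the discordant total `b+c` only, which is why
published marginal counts suffice to recompute it. The Clopper–Pearson
lower bound uses the beta-quantile form `qbeta(alpha, x, n−x+1)` with the
`x = 0 → 0` convention.

# The digital phantom

The generator emulates the anatomy the planning metrics depend on: a chest
slab (y ≥ chest plane), a hemispherical breast attached to it, a 2 mm skin
shell, a paraboloidal nipple bump at the apex, a fibroglandular ellipsoid
reaching the inner skin at the apex (the retroareolar configuration the
nipple heuristic exploits), adipose fill, cylindrical vessels, and
ellipsoidal tumor foci. Stamping precedence is air < chest < adipose <
fibroglandular < vessel < skin < tumor, so every voxel receives exactly one
label; tumors are validated to lie strictly inside the breast interior, so
the skin/tumor precedence question never arises. Optional seeded Gaussian
jitter perturbs the breast radius per voxel (default 0: analytic shapes for
property tests, noisy ones for robustness tests).

Ground truth is computed from the continuous geometry: ellipsoid volumes in
closed form, tumor-to-chest from the slab plane, tumor-to-skin via the
maximum distance from the breast center to the tumor ellipsoid (1D
root-finding on the Lagrange condition), tumor-to-nipple via point-to-
ellipsoid projection. The nipple reference is the continuum limit of the
detector itself — the centroid of the region within 8 mm of the air, skin
and fibroglandular *regions*, computed by 0.5 mm quadrature independent of
the label grid, plus the 6 mm offset — stored alongside the anatomical
apex (hemisphere pole) and the bump tip. Defining the distance truth
through the detector's continuum limit is deliberate: the pipeline measures
distance to the detected nipple, and the voxelization error of that
measurement is only interpretable against the same functional.

Preset geometry was fixed by design-time constraints, not fitted to
outcomes: tumor radii are at least 6 mm so that 1 mm voxelization keeps
volume error within the 5 % validation tolerance (a 5 mm sphere already
incurs ~5 % error purely from sampling); multifocal-near foci sit 6.8 mm
apart (a 5 mm margin must merge them) and multifocal-far foci 45.9 mm apart
(more than twice the 20 mm maximum margin, so they never merge); the
bilateral preset mirrors a standard breast on both sides of the centered
midline. Unilateral presets use a 110×96×110 grid at 1 mm with
`midlineIndex = 0`; tests that sweep spacing use a smaller 64×56×64
single-breast configuration at 2, 1 and 0.5 mm, sized so the full sweep
stays inexpensive.

What passing phantom tests establishes — and what they do not: the phantom
has exact class boundaries, no intensity information, no segmentation
noise, no motion or bias artefacts, and idealized smooth anatomy. Tests
against it verify that the *geometric measurement machinery* is correct
(volumes, distances, planes, hulls, boxes converge to analytic truth as
resolution improves). They say nothing about segmentation quality on real
DCE-MRI, reader behaviour, or population anatomy; those require clinical
cohorts, which is exactly why the reproducible statistics here are the
reader-agreement numbers (pure functions of published counts) and not the
cohort-level Dice/Hausdorff medians.

# Numerical conventions collected

* Voxel centers at `(i−0.5)s`; corners on the spacing lattice; extents are
  outer-edge spans.
* Half-space tolerances: `1e-9` mm for vertex-in-hull, hull overlap and
  voxelization.
* Quickhull visibility epsilon: `1e-9 ×` cloud diagonal.
* Balance-plane tolerance 0.5 % of tissue volume; rotation range ±45°;
  bisection cap 60 iterations; grid-scan fallback at 0.5° with a flag.
* Ties: balance plane → medial; transverse plane → lower; center of mass on
  a plane → upper/outer with a flag; dominant-mass ties → earlier raster
  component; anterior-point ties → smallest k then i.
* Distances reported in mm; no rounding is applied internally (the CLI
  reports full precision and leaves formatting to consumers).
* Empty-vs-empty Dice = 1.0, flagged; empty masks are errors for boundary,
  Hausdorff and distance operations.

# Known limitations

* Only axis-aligned orientations are supported; oblique scans must be
  resampled upstream.
* The quadrant and box procedures presuppose a roughly sternum-centered
  bilateral acquisition or an explicit midline.
* Margin hulls are convex by construction; concave resection shapes and
  cosmesis scoring are out of scope.
* The phantom's nipple bump attaches to the hemisphere at a point, leaving
  a small air crevice at its rim — harmless for the adjacency-based
  detector but not anatomically faithful.
* Hausdorff is the maximum variant; average or percentile Hausdorff is not
  provided.
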