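---
title: "Methods: 3D morphometry of mitochondria and mitochondria-ER contacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D morphometry of mitochondria and mitochondria-ER contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mitomorph` quantifies mitochondrial shape and mitochondria–ER contact sites
(MERCS) in segmented 3D electron-microscopy label volumes. This vignette is
the package's account of its methods: the measures and their assumptions,
the tunable parameters, what the synthetic generator does and does not
emulate, and the numerical choices behind the implementation.

## Input model

The unit of input is a `label_volume`: a 3D integer grid (0 = background)
with physical voxel spacing in nm, axis order (z, y, x), z being the
sectioning axis. The reference acquisition geometry is 8 × 8 nm pixels at
50 nm sections, i.e. 6.25-fold anisotropy — which is why every metric in the
package is computed in physical units and never from voxel counts along
axes. A voxel's physical center is `(index − 0.5) × spacing` per axis
(1-based indices).

Objects are connected components of equal-labeled voxels under
**26-connectivity**; corner contact joins thin oblique structures across
sections the way interactive tracing tools do, whereas 6-connectivity would
fragment the thin MOAS necks this package exists to detect. Objects touching
any grid face are excluded from measurement runs by default. This
boundary-touching rule is a proxy for the manual criterion of excluding
objects with incomplete borders — the only automatable reading — and the
count of exclusions is carried into every report so the proxy is visible.

## Shape measures

- **Volume** is exact in the voxel model: voxel count × voxel volume.
- **Surface area** comes from a triangle mesh extracted at iso-level 0.5 by
  marching tetrahedra on the Kuhn (6-tetrahedron) cell decomposition, after
  one pass of a 3-voxel box filter. Plain voxel-face counting overestimates
  the area of a sphere by roughly 50% and never converges; the smoothed
  iso-surface measures a 0.5 µm ball on an 8 nm grid to within 0.4%. The box
  filter is symmetric, so a flat axis-aligned interface keeps its 0.5
  crossing exactly midway between voxel centers (no bias), while curved
  surfaces gain sub-voxel interpolation. If smoothing collapses a structure
  thinner than one voxel, the mesh falls back to the raw binary surface; a
  single-voxel object falls back to the analytic area of the inscribed
  ellipsoid.
- **Length** is the maximum pairwise distance between boundary-voxel
  centers: exact brute force up to 5000 boundary points, beyond that an
  extreme-point prescreen along 1024 Fibonacci-sphere directions (relative
  error below ~0.2%, versus the ~1% discretization noise of the voxelization
  itself).
- **Aspect ratio** divides the length by the maximal extent perpendicular to
  the major axis. The perpendicular projection uses the first principal axis
  of the voxel centers as the major-axis *direction*: the farthest-pair
  direction itself is unstable (near-tie endpoint pairs on a capsule tilt it
  by tens of nm, inflating the minor axis by 30%), while the principal axis
  is rotation-invariant and recovers AR = 10.0 for a 2 × 0.2 µm capsule. A
  `method = "pca"` alternative reports extents along the first two principal
  axes instead. Collinear degenerate objects floor the minor axis at one
  voxel diagonal and are flagged.
- **Sphericity** is `ψ = π^(1/3) (6V)^(2/3) / SA`. With the mesh-based SA
  the measured ψ of a discretized sphere can exceed 1 slightly; the
  documented discretization slack is ε = 0.02 at ≤ 8 nm effective
  resolution, and the test suite holds all fixtures to ψ ≤ 1.02.

## Skeleton radius profiles and MOAS detection

MOAS ("mitochondria-on-a-string") are strings of ~0.5 µm beads joined by
~65 nm necks. They are detected structurally, not by length:

1. The object mask is resampled (nearest neighbor) to an isotropic grid at
   the finest spacing axis. Thinning on a 6.25:1 anisotropic grid would bias
   the medial axis toward the cheap direction.
2. An exact Euclidean distance transform (Felzenszwalb–Huttenlocher,
   generalized to per-axis steps) gives every voxel its distance to the
   background in nm.
3. A centerline is traced in the spirit of TEASAR: Dijkstra paths whose edge
   costs are length × (1 + γ(1 − EDT/EDTmax)²), γ = 50, pulling the path
   onto the medial axis; the primary path joins the two geodesically most
   distant voxels, and branch paths are added until every voxel lies within
   `cover_slack` × (local radius) of the skeleton. `cover_slack` defaults to
   1.2 because 26-neighborhood lattice geodesics overestimate Euclidean
   distance by up to ~8%; at 1.0 the overestimate spawns spurious branches
   inside large beads, each of which would be miscounted as an extra bead.
4. Node radii are first taken from the distance transform (minus half a
   voxel, since the transform measures to background voxel *centers*) and
   then refined to the exact distance from the node to the sub-voxel
   iso-surface mesh. The refinement matters at the acceptance tolerance: on
   an 8 nm grid the raw EDT recovers a 500 nm bead diameter at ~484 nm,
   the mesh distance at ~491 nm, against a one-voxel-diagonal (±14 nm)
   tolerance.

Bead/neck calling walks each maximal path: runs with radius ≥
`bead_min_radius_nm` (150) are beads; runs with radius ≤ `neck_max_radius_nm`
(45) and arclength ≥ `neck_min_run_nm` (100) are necks, and a neck counts
only if beads flank it on both sides along its path. The radius thresholds
derive from the nominal geometry — bead ~0.5 µm across (min radius 150 nm
admits tapered, teardrop-like beads), neck ~65 nm across (max radius 45 nm
admits the 32.5 nm nominal radius plus roughly one voxel of distance-field
overestimate) — because the source description gives shapes, not detector
thresholds, and the defaults must accept the nominal geometry with margin.
The 100 nm run gate rejects single-node dips on anisotropic data. Necks
longer than 5 µm still count but are flagged rather than reclassified: the
upper bound on neck length is descriptive, not definitional.

## Classification

Decision order: the structural MOAS test first (≥ 2 beads and ≥ 1 neck →
Type IV, regardless of length), then length: Type I up to
`type1_max_length_um` inclusive, Type II strictly below
`type2_max_length_um`, Type III at 5 µm and beyond ("5 µm or longer" is a
closed lower bound). Two presets exist because the class bounds are reported
differently in different places: `"methods2015"` (Type I ≤ 0.5 µm, default)
and `"results2023"` (Type I < 1 µm); the active preset is recorded in every
report. Classification is by length plus bead/neck structure; aspect ratio
and volume are reported as descriptors rather than used as decision
variables, since length boundaries are the only quantitative definitions
given. The classifier is total (every object gets exactly one type) and
deterministic.

## MERCS detection and quantification

Gaps are measured **surface to surface**: from each face centroid of the
mitochondrion's iso-surface mesh to the nearest point of the ER iso-surface
mesh. A 25 nm criterion applied to voxel-center distances would be
meaningless at 50 nm section thickness; both meshes interpolate at sub-voxel
precision, and on a 2 nm validation grid the measured minimum gap reproduces
the generated surface distance exactly (24 nm → 24.000, 26 nm → 26.000),
so the detection boundary brackets the criterion to one voxel diagonal.
For efficiency, face centroids are prescreened by a voxel distance
transform of the ER (which can underestimate the surface gap by at most half
a voxel diagonal) before the exact mesh query; distances beyond a cap
(criterion + 4 half-diagonals by default) are reported as `Inf`.

Contact faces (gap ≤ `max_gap_nm`, default 25) are grouped into patches by
shared-edge adjacency and split by ER object id, so one mitochondrion
apposed to two ER tubules yields two MERCS. Per patch:

- **area** = summed face areas; per-mitochondrion **coverage** = 100 ×
  (summed contact areas) / SA, the 3D surface reading of "perimeter
  covered";
- **length** = maximum pairwise distance between member-face centroids, the
  end-to-end extent of the freehand line a human would draw;
- **volume** = summed volume of the ER voxels of the partner object whose
  boundary lies within the criterion of this mitochondrion, attributed to
  the nearest patch. The quantity "MERCS volume" is under-defined in the
  literature (ER-side, mitochondrion-side, or gap-slab); this package uses
  the ER-side reading and says so in every report manifest, so comparisons
  against differently defined volumes are understood as qualitative.

Contact lengths are averaged per mitochondrion in `mercs_coverage()`, and
pooled summaries (`mercs_by_type()`) report mean ± SEM for Types I–III
together and MOAS separately, with empty pools absent rather than zero.

## Group statistics

`summarize_group()` reports mean ± SEM (n − 1 denominator; SEM absent for
n = 1). `one_way_anova()` is the classical fixed-effects F test.
`one_sided_t()` is the pooled-variance unpaired Student's t — pooled because
that is the named test; Welch and two-sided forms sit behind flags. The
direction of every one-sided test must be stated explicitly; there is no
silent default. Degenerate zero-variance comparisons define t = 0, p = 0.5,
flagged. No multiple-testing correction is applied by default (tests are
reported per comparison); `pairwise_tests(..., adjust = "holm")` enables
Holm's correction and the output records which policy was used.

## The synthetic generator

`rasterize_scene()` builds co-registered mitochondria/ER label volumes from
continuous geometry: spheres (Type I), capsules (Types II/III), and MOAS as
unions of bead spheres and neck cylinders. A voxel is labeled iff its
physical center lies inside the continuous shape — the center-in-shape rule
keeps volume estimates unbiased (any-overlap rasterization would dilate
every object by up to half a voxel). Beads are spheres rather than literal
teardrops: the classifier consumes bead/neck radii, for which the taper is
immaterial; this is a documented divergence from the descriptive shape.

ER placements position a tube parallel to a target shape at a requested
surface gap. Because binary iso-surfaces sit midway between voxel centers,
achievable rasterized gaps are quantized by the grid; the generator records
both the requested and the *achieved* gap (closed form from the lattice
phase), and the ground truth is the achieved value. On an 8 nm grid,
requested gaps of 24 and 26 nm rasterize identically — which is why the
detection-boundary validation runs on a 2 nm isotropic grid, where every
even-valued gap is achieved exactly. `sample_population()` draws n objects
at stated type fractions (multinomial, one seed governs all randomness) with
size jitter inside class bounds: spheres 0.32–0.48 µm, Type II tubules
0.9–4.5 µm × 0.18–0.3 µm, Type III 5.3–6.5 µm, MOAS with 2–4 beads of
0.45–0.55 µm, necks 60–70 nm × 0.3–0.7 µm. The jitter bounds keep each
object unambiguously inside its nominal class so that generator truth is
well-defined; neck length is treated as a free parameter below 5 µm with no
claim about its biological distribution.

What the generator does **not** emulate: image noise, membrane texture,
segmentation errors, touching organelles, curved or branched tubules,
teardrop bead asymmetry, ER sheets and fenestrated networks. Passing tests
therefore demonstrate that the measurement and classification machinery is
correct on clean geometry at realistic scales and spacings — not that the
pipeline is robust to segmentation quality, which is a property of the
upstream tracing, nor that the type taxonomy captures every real morphology.

## Numerical choices and degenerate inputs

- Rasterization uses closed inequalities (surface points are inside).
- Length boundaries: 0.5 µm ties go to Type I; exactly 5 µm is Type III.
- Iso-level ties cannot occur: box-filtered binary fields take values k/27
  per pass, never exactly 0.5.
- Empty volumes yield empty object lists and empty tables, not errors; an
  ER-free scene yields all-infinite gaps and zero contacts.
- Single-voxel objects: analytic-ellipsoid surface area, single-node
  skeleton flagged `low_confidence`, bead iff its radius passes the bead
  threshold.
- Report regeneration is byte-identical for identical inputs (no
  timestamps; deterministic ordering).

## Problem sizes in the tests

The suite validates on: 0.3–0.5 µm spheres and 2–6 µm capsules at 8 nm
isotropic; the four-type fixture panel (~15M voxels, 8 nm); MOAS at nominal
geometry (~390k object voxels); contact fixtures at 2 nm isotropic
(~7M voxels) where gap quantization vanishes; and a 25-object mixed
population at the acquisition spacing (50, 8, 8) nm, on which classification
recovers generator truth at ≥ 95% (observed: 100%). These sizes were chosen
as the smallest at which discretization error is comfortably below each
test's tolerance.

## Known limitations

- The boundary-exclusion rule is a proxy; organelles with complete borders
  that merely touch the crop are also excluded.
- Contact "length" is the patch diameter in 3D; a geodesic (on-surface)
  length and a per-section 2D perimeter mode are natural extensions not
  implemented here.
- Amira's surface-area algorithm is unpublished; absolute SA (and hence ψ)
  may differ from Amira outputs by a method-dependent factor, so ψ
  comparisons across software are relative.
- Skeleton branch handling is sufficient for strings and tubes; heavily
  branched mitochondrial networks (rare in dendrites) would need a fuller
  junction-aware bead accounting.
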