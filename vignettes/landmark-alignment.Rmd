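---
title: "Landmark-based head CT alignment: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based head CT alignment: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctalign)
```

## The alignment model

`ctalign` rigidly aligns a head CT from three bony landmarks: the right
cochlea, the left cochlea and the nasal bridge. These structures are
chosen because they are compact, high-contrast and nearly invariant in
shape, and because the plane they span approximates the orbito-meatal
scanning reference, so aligning them also brings the whole head close to
the standard AC-PC-like viewing orientation.

All geometry lives in the LPS frame (+x = patient left, +y = posterior,
+z = superior). A volume is a 3D array plus spacing, origin and an
orthonormal direction matrix; voxel *centers* at 0-based index (i,j,k)
map to physical millimetres as `origin + direction %*% (spacing * c(i,j,k))`.
That single mapping backs every operation in the package, which is what
makes centers of mass, resampling and analytic point propagation mutually
consistent.

The alignment target is: cochleas at equal y and equal z (mirror
symmetry across the sagittal plane), and nasal bridge at the same z as
the right cochlea (all three landmarks on one axial plane). The default
`sequential` mode reaches it with three plane rotations about the
inter-cochlear midpoint, applied in fixed order — axial (yaw, about z),
then sagittal (pitch, about x), then coronal (roll, about y) — each
computed on the landmark positions left by the previous rotation, and
composed into the single matrix `R_y(roll) %*% R_x(pitch) %*% R_z(yaw)`.
The composite is applied to the image in exactly one interpolation pass:
chaining three separate resamples would accumulate interpolation error,
which the test suite demonstrates directly by comparing label centers of
mass against analytically transformed points.

The rotation center is the inter-cochlear midpoint. No center is
canonical for this family of methods; the midpoint keeps the structures
of interest fixed, makes yaw and roll symmetric about the cochlear axis,
and costs nothing in generality since a pure rotation about any center
differs only by a translation. For the same reason the method has no
translation or scaling component at all: physical dimensions are
preserved exactly, which is a requirement for quantitative use.

Angle branches are always the solution within ±90°, with anatomical
guards: the left cochlea must stay on the patient's left and the nasal
bridge anterior. This avoids spurious 180° flips on near-aligned inputs
and turns genuinely ambiguous geometry (cochleas stacked vertically,
collinear landmarks) into explicit degenerate-geometry errors rather than
silent misalignments.

## Sequential residual and the exact mode

The sequential procedure is not a perfect solver of its own target. Yaw
equalizes cochlear y; the subsequent pitch, rotating about x, re-tilts
the cochlear axis and re-introduces a y deviation of exactly

&nbsp;&nbsp;&nbsp;&nbsp;`|Δz| * |sin(pitch)|`

where `Δz` is the cochlear z gap before pitch (yaw does not change z).
Roll, applied last, zeroes the cochlear z gap exactly — but in doing so
shifts the nasal bridge off the cochlear axial plane by a term
proportional to `sin(roll)` times the bridge's x offset from the rotation
center. Both residuals are sub-voxel for clinically plausible geometry,
which is why landmark alignment of this form reports mean cochlear
deviations of a few tenths of a millimetre rather than zero even with
perfect landmarks. The property suite verifies the y-residual law to
1e-9 mm on 1000 random geometries.

The package therefore also provides an `exact` mode: build the
orthonormal frame `e1 = unit(l − r)`, `e2 = unit((b − r) ⊥ e1)`,
`e3 = e1 × e2` and rotate it onto `(1,0,0)`, `(0,−1,0)`, `(0,0,−1)`. This
closed form satisfies all three constraints simultaneously to machine
precision and doubles as the independent oracle for the sequential mode.
A useful identity, proved in the tests: the exact rotation equals the
sequential rotation composed with one further yaw-then-pitch correction,
i.e. a second sequential pass lands exactly on the exact solution, and
the geodesic gap between the two modes is bounded by the sum of those two
correction angles.

## Tunable parameters

* `mode` (`"sequential"`, default): the plane-by-plane method; `"exact"`
  is the closed-form variant.
* `expand_z` (default `TRUE`): grow the output grid along z until every
  rotated corner of the input extent is covered, so no craniocaudal data
  is lost; new voxels are filled with −1024 HU (air). The x-y extent is
  kept, matching how aligned studies are reviewed.
* `fill` (default −1024 for images, 0 for labels): the out-of-extent
  value. CT convention; the choice only affects voxels with no source
  data.
* `sagittal_offset_deg` (default 0, allowed within ±15): a constant
  pitch added after alignment. The cochlea-nasal bridge plane sits about
  5° counter-clockwise of the true AC-PC plane on average, so users who
  prioritize brain orientation over skull-base symmetry can pass
  `sagittal_offset_deg = 5`; it is exposed as a plain offset, not a
  validated correction.
* `diameter_mm = 10` in `sphere_label()`: the annotation ROI is a 1 cm
  sphere, read as *diameter* (the colloquial reading of "a 1 cm sphere");
  at the 1.5 mm working resolution the distinction only rescales label
  volume, not its center of mass.
* Detection threshold in `detect_landmarks_oracle()`: midway between the
  skull and landmark-sphere intensities; tests show centers of mass are
  stable to ±10% threshold perturbation.

## Landmark detection

Landmarks enter as binary label maps — manual annotations, phantom
spheres, or the output of any segmentation model — and are reduced to
points by the center of mass of the largest 26-connected component. The
largest-component rule guards against speckle in predicted labels;
binary (unweighted) averaging is used because the labels are spheres by
construction. An empty label map raises a "landmark not found" error,
the machine-detectable analogue of real-world failures on absent or
deformed anatomy (infant skulls, fractures, labyrinthectomy); batch
commands log such cases and continue.

Training a 3D U-Net per landmark is how detection is automated on
patient data, but a deep-learning stack is deliberately outside this
package's dependency footprint, and phantom spheres need no learning:
the included threshold-plus-components oracle detector covers every code
path that network predictions would exercise (label maps in, points
out), keeping the full pipeline testable end to end without trained
weights or patient data.

## The synthetic phantom

`generate_phantom()` builds a schematic head: an ellipsoidal bony shell
(default semi-axes 70 × 85 × 55 mm) with a soft-tissue interior, a small
anterior bony wedge at the nasal ridge, and three high-density spheres
(2000 HU, 10 mm diameter) at the landmark positions, on a 128 × 128 × 80
grid at 1.5 mm isotropic spacing — the working resolution of the
alignment pipeline. Default landmark geometry: cochleas 60 mm apart at
the skull base, nasal bridge 70 mm anterior on the cochlear axial plane.
The canonical pose is deliberately the *aligned* pose (nasal bridge
craniocaudal offset 0), so a recovered alignment can be compared
directly against the applied misalignment and "restored to canonical
orientation" is well defined.

`apply_misalignment()` rotates the volume once (trilinear, z-extended)
while transforming the true landmark coordinates analytically; sphere
centers are therefore known exactly at every stage and image-derived
centers of mass are only used where detection itself is under test. The
misalignment envelope is ±45° per plane, the same envelope the detection
model is trained to tolerate via augmentation.

What the phantom does *not* emulate: CT noise and texture, beam
hardening, anatomical variability of real cochleas, partial-volume
effects at real bone interfaces, and pediatric (incompletely ossified)
skulls. Passing phantom tests therefore demonstrates the geometry —
detection-to-point reduction, rotation computation, single-pass
resampling, evaluation — not segmentation performance on patients; the
published patient-cohort numbers require real data and trained models
and are out of scope here.

## Evaluation and statistics

Skull-base alignment is scored as the absolute cochlear y and z
deviations in mm (perfect alignment = 0 on both axes). Whole-head
alignment on phantoms replaces human raters by the analytic residual:
compose the recovered rotation with the applied misalignment and
decompose under the same z → x → y convention into axial/sagittal/
coronal angles. The manual-measurement reporting convention is kept so
outputs are comparable: clockwise is positive, degrees are rounded to
whole numbers, half away from zero (the rounding rule is a package
choice; only "whole numbers" is inherited).

Cohort comparisons use the paired Wilcoxon signed-rank test on
*absolute* deviations, because signed clockwise/counter-clockwise errors
cancel in the mean and understate misalignment. Zero differences are
dropped (standard convention). With ≤14 informative pairs the two-sided
p-value is computed by full enumeration of all 2^n sign assignments,
which remains exact under tied ranks; larger samples fall back to
`stats::wilcox.test`. A Shapiro-Wilk gate at α = 0.05 documents the
normality check that motivates the nonparametric choice. Interrater
reliability uses ICC(1,k) — one-way random effects, average measures,
absolute agreement — implemented from the one-way ANOVA mean squares
with the standard F-based confidence interval, and cross-checked in the
tests against both a hand-coded ANOVA oracle and an independent
reference implementation.

## Numerical choices and degenerate inputs

* Orthonormality of rotations is enforced to 1e-9 and determinant +1 to
  1e-9; analytic landmark propagation is exact (no grid involved).
* Trilinear interpolation is used for images, nearest-neighbour for
  labels; labels are never linearly interpolated, so label values stay
  binary through any resampling.
* Out-of-extent samples get the fill value; the interpolation domain is
  the hull of voxel centers with a 1e-9 index tolerance so on-grid
  points never fall out.
* Euler decomposition (z → x → y) refuses |pitch| beyond 89.9° (gimbal
  neighbourhood); alignment itself never produces such angles for valid
  anatomy because branches are capped at ±90°.
* Degenerate landmark configurations — coincident points, collinear
  landmarks, cochleas stacked in a plane that makes an angle undefined —
  raise errors naming the failing constraint rather than guessing.
* Reorientation to LPS is a pure index permutation/flip and refuses
  oblique volumes (off-axis cosines beyond 1e-3) instead of silently
  resampling.
* The 1 cm annotation sphere is read as diameter (radius 5 mm), and the
  working resolution is fixed by physical spacing (1.5 mm isotropic)
  rather than matrix size, since physical units are what the geometry
  consumes.

## Problem sizes used in validation

The test suite validates analytic properties on 100–1000 randomly
generated landmark geometries (they cost microseconds), and volumetric
properties on default-resolution phantoms: 50 misalignment-recovery
cases over 10 phantom variants, 20 composite-versus-chained resampling
trials, and 4 label-resampling checks of the perfect-alignment
definition. Unit tests use a coarser 64 × 64 × 40 grid at 3 mm with the
same physical extent, which exercises identical code paths at lower
cost. These sizes are the package's own validation design; the
generator accepts arbitrary grids.

## Known limitations

* Detection here is the phantom oracle; applying the package to patient
  CT requires an external landmark segmentation (any model producing
  NIfTI label maps plugs in via `label_center_of_mass()`).
* Only NIfTI I/O is supported; DICOM series must be converted upstream.
* The method guarantees alignment of the three landmarks only;
  structures far from them are aligned only to the extent skull anatomy
  is rigidly consistent.
* Repeated alignment of longitudinal studies is not guaranteed to land
  on identical orientations; the serialized transform
  (`write_transform()`) supports re-applying an initial alignment
  instead.
* Template registration (similarity-transform baselines) is not
  re-implemented; `cmd_evaluate()` accepts landmark sidecars produced by
  any external method for comparison.
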