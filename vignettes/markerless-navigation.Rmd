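---
title: "Markerless surface-based navigation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless surface-based navigation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(surgnav)
```

## The problem

Frameless neuronavigation overlays a preoperatively planned biopsy
trajectory on the patient. Marker-based systems register the plan to the
patient by touching fiducials or tracing the skin with a tracked pointer;
markerless systems instead align the skin surface extracted from the
preoperative scan directly to a live depth-sensor point cloud. surgnav
implements that markerless pipeline end to end — in silico — together with
the instruments needed to measure how well it navigates: a procedural head
phantom with conical measurement fiducials, a depth-sensor simulator, and
the off-plan-distance error metric.

Everything is metric: coordinates are millimetres in a right-handed frame
with +x right, +y anterior (facial direction), +z superior. Poses are
rigid transforms (`R`, `t`), rotations stored as matrices and checked
orthonormal to 1e-9; quaternions are accepted at I/O boundaries and
normalised on ingest.

## Error metrics

The primary metric is the **off-plan distance**: the shortest Euclidean
distance from a measured probe tip to the planned trajectory. The
trajectory is treated as the *infinite line* through the planned entry and
target points, not the segment — a navigated probe is aligned with the
trajectory's line, and its tip is typically short of the entry point when
the measurement is taken on the skin. A segment-clamped variant is
available behind `off_plan_distance(..., segment = TRUE)` for
completeness. The **entry-point offset** is the Euclidean distance between
an overlaid entry point and its reference position; it is invariant under
a common rigid motion of both, which the tests assert.

## The digital head phantom

`generate_head_phantom()` builds a watertight, genus-0 head: an icosphere
is scaled to the head extents (default 160 x 195 x 225 mm) and displaced
radially by a facial relief pattern — protrusive nose tip and ridge below
the eye line, brow, forehead dome, narrow chin, cheekbones, recessed eye
sockets and mouth — plus a few seeded low-amplitude bumps that make every
phantom individual. The relief is deliberately asymmetric top-to-bottom:
surface registration of a (near-)symmetric surface is ill-posed, and an
early symmetric draft of this generator demonstrated exactly that failure
mode by letting a 180-degree in-plane flip fit the face within ~2 mm. The
`feature_amplitude_mm` knob (default 12 mm) scales the relief; the mesh is
rescaled per axis at the end so the bounding box matches the requested
extents exactly.

`place_fiducials()` distributes 51 conical measurement points over the
face and scalp by farthest-point sampling with a 15 mm minimum spacing
(the published phantom does not give its point coordinates, so a
deterministic, seeded placement stands in). Each cone apex lies exactly
20 mm below its skin opening along the inward normal, with a 0.2 mm
cone-margin recorded as metadata; candidate sites are rejected when the
apex would clear the surface by less than 19 mm (which rules out
high-curvature sites such as the nose ridge) or fall outside the head.
`plan_trajectories()` connects each opening's centre to its apex — a 20 mm
trajectory whose target is, by construction, on its own line.

`voxelize()` rasterises the phantom into a scalar volume by x-ray parity
per voxel row (the mesh is watertight by construction). The default pitch
is the 0.5 mm isotropic grid of the preoperative scans; the anisotropic
1.0 x 0.5 x 0.5 mm grid of a CT of the printed phantom is equally
supported. Intensities default to inside 100 / outside 0 with optional
Gaussian noise (sd 5) — only threshold separability matters downstream.

### Skin shift

Patient positioning deforms the facial and scalp soft tissue relative to
the preoperative scan, and published navigation errors grow toward the
dorsum. `deformation_field()` models this as a sum of up to five Gaussian
radial-basis displacement bumps (default sigma 60 mm) with seeded centres
and directions. The amplitudes are normalised so the *peak* displacement
over the domain equals `max_magnitude_mm` (a raw sum of bump amplitudes
reaches its nominal value nowhere), and a hard clamp guarantees the bound.
Posterior weighting multiplies the field by a smooth quadratic ramp (floor
0.05) along the anterior-posterior axis, so the regional gradient
dominates the seeded bump-placement variation rather than being washed out
by it.

## Surface extraction

The preoperative chain mirrors standard skin-model preparation:

1. `threshold_segment()` — intensity threshold, then the largest
   26-connected component (an automated, reproducible stand-in for manual
   threshold segmentation; the threshold is a config value, default 50).
2. `median_smooth()` — per-voxel majority vote in a cubic window whose
   edge is 3 mm converted to voxels per axis, rounded to the nearest odd
   integer (minimum 3), clamped at the borders. For a binary mask the
   windowed median *is* the majority vote, computed here by separable
   running box sums.
3. `extract_surface()` — internal cavities are filled by flood-filling the
   6-connected background from the volume border and inverting (the
   "solidify" step), the indicator is box-smoothed twice to suppress the
   voxel staircase, and the 0.5 iso-surface is extracted by **marching
   tetrahedra** on the Kuhn 6-tetrahedron cube split. This member of the
   marching-cubes family was chosen because it needs no ambiguous-case
   lookup tables and the translation-invariant split makes the surface
   watertight by construction; with the pre-smoothing, the extracted
   sphere's area is within 5% of its analytic value, which the tests pin.
4. `decimate()` — quadric-error-metric edge collapse with link-condition
   and normal-flip guards, down to the 100,000-triangle budget used for
   reference skin models.
5. `crop_reference()` — the two reference-model styles: `face_only` keeps
   the surface anterior to the coronal plane through the landmarks, and
   both modes delete the two 15 mm eye-exclusion spheres (eye regions are
   unreliable for depth registration). Landmarks are auto-estimated on
   head-like meshes (most-anterior midline vertex for the nose, socket
   directions for the eyes, centroid plane for the ears).

## Depth-sensor simulation

`depth_camera()` is a pinhole model, by default 320 x 288 pixels with a 75
degree horizontal field of view — loosely the class of head-mounted
time-of-flight sensors; every intrinsic is configurable. `render_depth()`
casts one ray per pixel through a bounding-volume hierarchy and records
the depth along the camera z axis of the first hit (z-buffer semantics);
misses are 0. `depth_to_pointcloud()` inverts the projection into a world
point cloud. `corrupt()` applies the noise model: axial Gaussian error
along the viewing ray (default sd 1 mm — time-of-flight noise is
predominantly axial; lateral jitter is a noted extension), 0.25 mm range
quantization, and 5% Bernoulli dropout, all seeded. `coverage_fraction()`
labels partial views; note an open reference shell cannot occlude itself,
so the full scene mesh is passed as the occluder.

## Registration

`register_pipeline()` is the automatic cascade:

sample the reference surface (20,000 area-weighted points) -> voxel
downsample both clouds (4 mm) -> covariance normals (k = 30) -> 33-bin
FPFH descriptors (radius 15 mm) -> mutual nearest-neighbour matching ->
robust global alignment -> ICP refinement -> numeric failure check.

Design choices that matter:

* **Normal orientation.** Both clouds use the same covariance estimator so
  their descriptor statistics are comparable. Orientation is made
  consistent by propagation over the minimum spanning tree of the kNN
  graph, and the global sign is fixed by a support-point vote (at the
  extreme point along any direction, the outward normal has a positive
  component along it) — this disambiguates closed heads and open face
  shells alike. When the sensor position is known it can be passed as a
  viewpoint instead.
* **Saliency filtering.** Only the 40% most distinctive histograms per
  side (largest L1 distance from the cloud's mean histogram) enter
  matching. Near-flat skin produces near-identical descriptors whose
  chance mutual matches otherwise flood the pool; the informative
  matches live on the nose, sockets, brow and chin.
* **Robust global stage** (`global_register()`): scale is fixed at 1 —
  same-patient rigid anatomy. Translation-rotation-invariant measurement
  pairs prune outliers through maximal cliques of the compatibility graph
  (edge when the pairwise-length discrepancy is within twice the noise
  bound, default 6 mm; igraph's exact branch-and-bound search). Because a
  near-symmetric pose can support a clique *larger* than the true one, up
  to four node-disjoint cliques are extracted by deflation (find, remove,
  repeat), each solved by graduated non-convexity over the truncated
  least-squares rotation cost (mu annealed from the max residual by
  factor 1.4 until the surrogate reaches TLS) plus per-component TLS
  translation voting, and re-fit on its consensus set.
* **Hypothesis verification.** Competing candidates are refined by a
  10-iteration ICP and scored by mean truncated distance to the raw
  scene; the best continues to full ICP. This replaces nothing in the
  happy path (one candidate short-circuits) and resolves the symmetric
  ambiguities measurably present on face-like surfaces.
* **ICP** (`refine_icp()`): nearest-neighbour correspondences within
  10 mm (lowest index on ties, for determinism), point-to-plane updates
  by a linearised 6x6 solve (point-to-point closed form available; its
  matched-pair RMSE sequence is non-increasing on full-overlap clouds,
  which the tests assert on 50 random trials), convergence at relative
  RMSE change 1e-6 or 50 iterations.
* **Failure check.** The operator's visual inspection ("does the virtual
  skin sit on the real skin?") is replaced by a numeric verdict: success
  iff the RMS distance of transformed model points to the raw scene
  (within the 5 mm overlap gate) is at most 3 mm AND at least 30% of
  model points are within that gate. Verdict residuals are computed
  against the full-resolution scene, not the downsampled clouds, so they
  reflect surface distance rather than sampling pitch.
* `register_with_fallback()` encodes the clinical protocol: one attempt
  with the face-only model, and on failure exactly one retry with the
  full-head backup model.

## The two study harnesses

`run_phantom_study()` reproduces the 51-point design: for each
within-system registration accuracy in 0.5-2.5 mm (step 0.5), one
registration perturbed to that accuracy (`perturb_to_accuracy()` scales a
seeded random rotation about the surface centroid plus translation until
the mean displacement of a skin-surface sample equals the target within
2%), then each of the 51 planned entry points is measured three times
with freehand probe jitter (isotropic Gaussian, sd 0.5 mm — the manual
pointer-placement component; an optional extra entry-planning jitter of
0.9 +/- 0.7 mm is available but off by default). 5 x 51 x 3 = 765
records. The summary reports per-level mean +/- SD, Spearman rank
correlation (average ranks, large-sample p), per-region means and failure
counts.

`run_patient_style_study()` simulates one subject per row: a fresh seeded
phantom; one trajectory in an assigned head region; a posterior-weighted
skin shift applied to the live surface; a frontal corrupted depth scan;
the full cascade run from a random unknown initial pose (up to 30 degrees
/ 100 mm) against a reference built through the volumetric chain, with
the full-head fallback on failure. The measurement model follows the
clinical mechanism: the tissue — and with it the *true* trajectory —
rides with the deformation, while the overlay presents the undeformed
plan; the probe is placed on the actual (deformed) skin at the overlaid
entry and jittered. Off-plan is then measured against the deformed
trajectory. Modelling the probe as a projection onto the deformed skin
*without* moving the truth would silently cancel the very displacement
component the metric measures — a trap worth documenting.

## Problem sizes and numerical choices

The default test and acceptance runs use: a 10,242-vertex study phantom
(subject phantoms 2,562); subject volumetric chains at 1.0 mm voxel pitch
(0.5 mm remains `voxelize()`'s default and the scan condition — the
registration consumes 4 mm-downsampled clouds, so the chain's pitch is
not a results-bearing parameter, and 1.0 mm keeps a 21-subject study in
minutes); 20 seeded scenes for end-to-end recovery; 100 correspondences
with 70% outliers for the estimator contract; 50 trials for ICP
monotonicity. Degenerate inputs are defined errors: trajectories need
more than 1e-6 mm separation, empty masks and meshes raise, a scene with
no correspondences yields a failure result rather than an exception, and
collinear normal neighbourhoods are flagged invalid.

## What the synthetic data does and does not show

The generator emulates the geometry of the task — facial relief,
conical fiducials at depth, partial noisy depth views, skin shift — and
the *structure* of both study designs. It does not emulate hair (which
corrupts real full-head models), skin specularity or sensor-specific
artefacts, patient motion during acquisition, or display/tracking errors
of an optical see-through headset; absolute error magnitudes here are
therefore smaller than, and not comparable to, clinical measurements.
What passing tests do show: the estimator contracts hold under heavy
outlier rates; the cascade recovers known poses from partial, noisy,
initially-misaligned views; the failure check catches an occluded face;
and the error metric behaves exactly as defined against brute-force
oracles.

## Known limitations

* FPFH neighbour search and matching are dense (O(n^2) in the
  downsampled cloud sizes); fine for the few-thousand-point clouds the
  pipeline produces, not for raw scans.
* The procedural face, however asymmetric, is smoother than a real face;
  registration difficulty is tunable only through `feature_amplitude_mm`
  and the noise model.
* Landmark auto-estimation assumes the phantom's frame; arbitrary
  clinical meshes would need explicit landmarks for `crop_reference()`.
* The depth simulator has no lateral jitter, motion blur or multi-path;
  axial noise plus quantization plus dropout is the v1 sensor model.
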