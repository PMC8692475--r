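---
title: "Validating 2D super-resolution ultrasound track maps against 3D micro-CT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SRUS track maps vs micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(srusct)
```

## The scientific setting

Ultrasound localization microscopy (ULM / SRUS) reconstructs vascular
maps below the acoustic diffraction limit from thousands of single
microbubble trajectories. Each contrast frame shows a sparse set of
point scatterers; localizing them with sub-pixel precision, compensating
tissue motion, and linking positions across frames yields trajectories
whose accumulation is the super-resolution image: a raster of bubble
counts (intensity), flow direction and speed per pixel.

Validating such images of a deep organ requires an independent reference
of the same vasculature. An ex vivo micro-CT of the contrast-cast organ
provides one, but the comparison is geometrically awkward: the SRUS
image is a 2D plane with a finite elevational thickness (modeled as a
15.3 × 21.5 × 1.8 mm rectangular slab), the CT is an isotropic 3D volume
(22.6 µm voxels), and the two are related by an unknown global
similarity transform (translation, rotation, isotropic scale). The
package implements the full comparison chain — co-registration, slab
maximum intensity projections, centerline projection, ROI dilation,
overlap percentages with a mirrored-ROI null control, 4-s.d. diameter
estimation and −3 dB line-profile widths — and, because the original
animal data are not publicly deposited, a synthetic kidney-like phantom
that generates every input with ground truth.

## The phantom: a stated world, not a fit

`generate_kidney_phantom()` builds paired arterial and venous trees by
recursive branching: renal branches from the hilum, segmental arteries
fanning from them, arcuate arteries branching laterally, cortical radial
arteries rising toward the cortex. The venous tree is a parallel offset
copy of the arterial tree at 1.5–3 artery radii (default 2), emulating
how large veins wrap their paired artery; each vein is re-anchored on
its parent vein so the tree stays connected. Vasa recta bundles are
straight parallel vessels spanning the medulla, stacked mainly in the
elevational direction, half descending (arterial, antegrade) and half
ascending (venous, retrograde). Anatomical realism is deliberately
limited to the features the comparison exercises: class-dependent radii
spanning ~100–1300 µm diameters (vasa recta ~25–30 µm), artery always
thinner than its paired vein, region partition into hilum / segmental /
inner medulla / outer medulla / cortex bands along the axial axis.

Key defaults and why:

* **Frame rate 54 Hz, gate 278 µm, ≥3 consecutive frames, slab
  15.3 × 21.5 × 1.8 mm, CT spacing 22.6 µm** — the published
  acquisition/processing values; treated as fixed constants.
* **Mean speeds (mm/s)** — arteries 12/10/7/4 by branching level, veins
  half that, vasa recta 1–1.5. The trackable limit is
  gate × frame rate = 0.278 mm × 54 Hz ≈ 15 mm/s; arterial speeds sit
  just below it so that pulsatility (a single 5 Hz sinusoid, rat-like,
  modulation 0.4 for arteries, 0 for veins) pushes systolic peaks above
  the limit — reproducing the in vivo observation that arterial tracks
  are harder to link and shorter than venous ones.
* **Bubble concentration** — the protocol states an infusion rate, not a
  per-frame count, and was "adjusted to have isolated MBs". The default,
  0.2 Poisson arrivals per frame, keeps roughly 10–25 concurrent
  bubbles in the slab; raising it by an order of magnitude demonstrably
  collapses track purity (merged blobs, chimeric tracks), which is the
  same failure mode the real protocol avoids by dilution.
* **Tissue motion amplitude 0.3 mm** — in vivo motion is never
  quantified; 0.3 mm is a plausible renal breathing-scale choice,
  flagged as an artifact default. The field is a spatially smooth random
  pattern (bilinear interpolation of coarse Gaussian knots, correlation
  length `smoothness_scale`) oscillating sinusoidally with a period of
  27 frames (~0.5 s); magnitude ≤ amplitude and discrete gradient ≤
  amplitude / smoothness_scale by construction.
* **Point-spread σ = 0.15 mm, acquisition pixel 0.1 mm** — consistent
  with a 6 MHz transmit (λ ≈ 0.25 mm).
* **Super-resolution pixel 25 µm** — about λ/10; the original grid size
  is unstated, so this is configuration with a documented default.

What the phantom does **not** emulate: acoustic wave propagation,
nonlinear bubble oscillation, amplitude-modulation sequences, speckle
statistics of real tissue (the motion-estimation texture is correlated
Gaussian noise), non-rigid specimen deformation between modalities, and
real anatomical topology. A green end-to-end test therefore establishes
that the *processing chain* is correct and self-consistent under known
geometry — not that the in vivo numbers are reproduced.

## Localization

`localize_bubbles()` thresholds a frame (default 0.5 × frame maximum, or
absolute), groups pixels into 8-connected components and estimates one
sub-pixel position per component. The plain intensity-weighted centroid
of a thresholded blob carries a grid-dependent truncation bias of up to
~0.2 px, which fails the package's own 0.05 px accuracy requirement, so
the estimate is refined by an iterative Gaussian-windowed centroid: a
Gaussian weight window (width from the component's RMS radius) is
re-centered on the running estimate until convergence. For a Gaussian
blob the fixed point of that iteration is the true center, and the
windowing stays robust at low SNR (measured: < 0.03 px noiseless,
~0.18 px RMS at 20 dB SNR on 0.1 mm pixels).

Two practical gates matter. `min_pixels` discards speck components, and
`min_amplitude` is an absolute noise floor: a purely fractional
threshold applied to a frame *without* bubbles sits at half the noise
peak and fires everywhere. Keeping the threshold above the noise floor
is the caller's responsibility; the pipeline default is
6 × the configured noise level.

## Motion estimation and compensation

`estimate_motion()` is classic speckle tracking: block-matching
normalized cross-correlation of each frame against a reference frame,
parabolic sub-pixel refinement of the correlation peak (skipped for
perfect integer matches, where the parabola vertex is spurious),
invalid flat-texture blocks inpainted from neighbors, 3 × 3 smoothing,
bilinear upsampling to the full grid. `compensate_detections()` moves
each detection back by the interpolated displacement at its (frame,
position); detections outside the motion grid use the nearest-edge
displacement. On the phantom, compensation reduces the RMS ground-truth
position error whenever the motion amplitude exceeds the localization
noise (0.3 mm amplitude → ~0.035 mm residual RMS).

## Tracking

`link_tracks()` implements a constant-velocity Kalman tracker with
optimal frame-to-frame assignment:

* per active track, a 4-state (position, velocity) Kalman filter
  predicts the next position;
* assignment between predictions and detections minimizes total
  Euclidean distance via the Hungarian algorithm (implemented
  in-package; verified against an exhaustive-permutation oracle);
* a **hard gate** is applied to the distance between the new detection
  and the track's *last detection*, so no emitted link can exceed
  278 µm regardless of the covariance state;
* unassigned detections seed new candidates; a track not extended in a
  frame terminates (no coasting — "consecutive frames" is taken
  literally, since gap tolerance is unknowable from the source);
* candidates shorter than 3 frames are discarded.

Kalman noise defaults (`process_noise = 20 mm/s²`,
`measurement_noise = 0.02 mm`) are set so the gate, not the covariance,
dominates; both are configuration. Ties in the assignment are resolved
deterministically by the algorithm's scan order (lower index first).

## Track maps, regions and artery/vein separation

`render_track_maps()` samples every link at half-pixel steps; a track
traversing a pixel counts one traversal regardless of how many of its
links touch the pixel, so intensity is "number of tracks through this
pixel" — additive across tracks. Direction uses circular (vector)
averaging, avoiding wrap-around artifacts at ±180°; speed is the mean
link speed of traversing tracks. Direction and speed are defined only
where intensity > 0.

`region_label_map()` labels the super-resolution grid with the
phantom's region partition and tiles each label into subregions, each
carrying a local arterial reference direction (length-weighted mean
tangent of arterial centerlines near the tile, window widened until an
artery is in reach). `separate_by_flow()` assigns each track to the
subregion holding most of its detections and classifies it arterial
when the angle between its mean direction and the reference is < 90°.
Tracks are partitioned, never dropped. On well-separated phantom flow
the classification accuracy exceeds 0.98; it degrades when paired
vessels lie closer than the point-spread width, because merged blobs
produce chimeric tracks — a physical limitation, not a classifier bug.

## Co-registration

`fit_similarity()` is the closed-form least-squares similarity fit
(cross-covariance SVD with the proper-rotation sign constraint).
Collinear landmark sets are rejected by name. The fitted transform
maps slab coordinates (axial, lateral, elevation ∈ [−0.9, 0.9) mm) into
volume coordinates; `invert_transform()` is exact to < 1e−9 mm on
round trips. A transform can also be supplied directly (JSON), so
manually co-registered real data can be imported.

`slab_mip()` samples the volume by trilinear interpolation along the
elevational segment of each in-plane pixel (step = half voxel spacing
by default; hard slab boundaries, half-open on the + side; optional
Gaussian elevation weighting was considered and rejected as the
reference procedure takes a plain MIP). Samples outside the volume are
−∞ (they never win the maximum); pixels entirely outside are invalid
(NA). `project_centerlines_to_plane()` maps polyline vertices through
the inverse transform, records slab membership with the same half-open
rule, splits polylines where they exit the slab, and preserves labels.

## Overlap metrics

* **ROI dilation** sweeps a disk of the class's radius along each
  projected centerline. The reference procedure dilated by "approximate
  expected vessel diameters" that were never tabulated, so the dilation
  table is explicit configuration; phantom experiments set it from
  ground-truth radii plus a stated margin (3 super-resolution pixels in
  the benchmark).
* **Centerline recovery** resamples query centerlines at half a pixel
  and reports the arc-length percentage landing on ROI pixels —
  independent of vertex density (the source's point-counting basis is
  unstated; arc length is the documented choice).
* **Track-map recovery** is the percentage of nonzero (optionally
  region-filtered) track-map pixels inside the ROI.
* **Mirrored-ROI control**: reflecting the ROI about the central axial
  axis (implemented as a left-right flip; both axes selectable)
  estimates chance overlap in a densely vascularized organ. On
  asymmetric phantoms the mirrored recovery falls tens of percentage
  points below the original — the qualitative signature of the real
  control.
* **Skeleton centerlines**: binarize, thin, trace branches between
  endpoints/junctions, prune below `min_branch_length`. Thinning is
  Guo–Hall (1989) rather than Zhang–Suen: the textbook Zhang–Suen batch
  update deletes 2 × 2 blocks wholesale and retracts 2-px-wide
  diagonals, both ubiquitous in rasterized vessel maps.
* **4-s.d. diameter**: four sample standard deviations of the
  *perpendicular* distances of bubble positions to their nearest
  centerline segment (whether the source used perpendicular or raw 2D
  scatter is unstated; perpendicular is adopted). Requires ≥10 positions
  (configurable); positions are assigned to a vessel within a capture
  radius of 2 × the dilation radius. Rotation/translation invariant by
  construction.
* **−3 dB width**: per profile peak, the width between the two crossings
  of peak × 10^(−3/10) on the *linear* intensity scale, linearly
  interpolated; log-compressed display images must be de-compressed
  first. Peaks are plateau-tolerant local maxima; boundary peaks get a
  flagged one-sided width.
* **Superposition counting**: the number of distinct labeled 3D
  polylines passing within a capture radius of an in-plane pixel at any
  elevation inside the slab — the mechanism by which several vasa recta
  bundles sum into a single SRUS pixel.

## Numerical choices and degenerate inputs

* Coordinates are right-handed mm; rasters are matrices with row =
  axial, col = lateral; pixel/voxel centers at origin + (index − ½) ×
  spacing; all cell and slab memberships are half-open `[lo, hi)`.
* Angles: 0° = +lateral, 90° = +axial, range (−180°, 180°].
* Randomness: one master seed per operation, with per-operation streams
  derived as `derive_seed(seed, tag)`; every operation is a pure
  function of (inputs, seed), and the caller's RNG state is restored.
* Degenerate inputs are contracts, not crashes: empty event lists render
  valid all-noise stacks; all-zero frames localize to empty detection
  sets; a phantom without segments rasterizes to a background-only
  volume with a warning; CT spacing above the smallest vessel radius
  warns that thin vessels may voxelize broken (the real resolution
  limit); zero-length queries and empty maps make recovery percentages
  `NA` with an `undefined` attribute rather than 0.

## Interchange formats

No TIFF/NIfTI reader is available in the target environment, so rasters
and volumes travel as plain CSV matrices (one file per frame/slice) with
a JSON sidecar carrying pixel size, frame rate, origin and spacing —
metadata is mandatory on import and never guessed; shape mismatches
error naming both shapes. Phantoms, centerlines and transforms are
schema-versioned JSON; events and tracks are CSV. Round trips are
bit-exact (`%.17g`).

## What the tests establish — and what they cannot

The acceptance suite checks gate invariants exactly, equivalence of the
tracker with an exhaustive-assignment oracle on sparse scenes,
localization and motion-compensation precision, exactness of the
similarity fit, calibration of the diameter and −3 dB estimators against
analytic laws, CT rasterization accuracy against πr², the superposition
counter against a brute-force oracle, and the end-to-end benchmark:
with a known transform and dilation = true radius + 3 SR pixels, vein
centerline recovery ≥ 95% and artery ≥ 90%; on laterally asymmetric
phantoms the mirrored-ROI control drops recovery by ≥ 25 percentage
points (median over 10 seeds). Simulated acquisitions are seconds long
(the in vivo scans were 10 minutes); the mirrored-control replicate
feeds ground-truth in-plane positions to the tracker directly to stay
inside the test-time budget. None of this reproduces the in vivo
percentages themselves — those depend on one animal's undeposited data,
manual annotation and imperfect registration, which the phantom, by
design, idealizes.

## Known limitations

* The phantom's region partition is a 1D axial banding, not real renal
  geometry; cortical radial vessels cross "medulla" bands on their way
  up, so region-filtered metrics should be interpreted against the
  phantom's own labels.
* Flow is kinematic advection (speed profiles along polylines), not
  hemodynamics; no dispersion within the tube beyond the fixed
  per-bubble offset.
* The tracker does not coast through missed frames; real modified
  Kalman trackers may.
* Registration is global similarity only, matching the reference
  procedure; non-rigid residuals in real data will lower overlap
  percentages for reasons the pipeline does not model.
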