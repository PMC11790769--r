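---
title: "Tracking and clustering rodent arena behavior: methods and design notes"
author: "arenatrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and clustering rodent arena behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arenatrack)
```

## The problem

Open-field (OF) and light–dark-box (LDB) tests quantify locomotion and
anxiety-like behavior from an overhead video of a rodent in an arena. The
standard readouts are the total distance traveled, the time, distance and
mean speed per region of interest (ROI — center vs periphery, lighted vs
dark), and the number of compartment transitions. Beyond these summaries,
subjects can be grouped *without supervision* by the similarity of their
trajectories or of their heading-angle dynamics, using dynamic time warping
(DTW) dissimilarities fed into k-means (with silhouette-guided model
selection) or agglomerative hierarchies.

This vignette documents the models, conventions and numerical choices the
package makes, and what its validation on synthetic data does and does not
establish.

## Detection model

The animal is assumed to be the only moving object in its arena and to
contrast with the floor. Detection per frame and arena is:

1. difference from a background reference, signed by polarity (`darker`
   keeps `background − frame`, `lighter` the opposite, `either` the
   absolute value);
2. binarization at a threshold θ (default 50 of 255 — high enough that
   Gaussian sensor noise with σ up to θ/3 essentially never crosses it,
   low enough that a dark animal on a light floor always does);
3. optional morphological open/close with a disc of radius *r* pixels
   (default 0; useful against speckle when noise is heavy-tailed);
4. connected components below `minBlobAreaPx` (default 5 px) are discarded
   — isolated noise pixels, droppings, small reflections;
5. the centroid of the *largest* surviving component is the position. The
   largest-component rule is the simplest resolution of multi-blob frames;
   it fails only if a non-animal artifact outgrows the animal, which a
   background re-estimate fixes.

The background comes from an animal-free leader frame (the recommended
recording practice is to leave the apparatus empty for a few seconds before
placing the animals), an external photo, or a per-pixel median over a frame
range — the median recovers the empty scene wherever the animal occupies a
pixel less than half the time.

Conventions: grayscale conversion uses the standard luma weights
(0.299 R + 0.587 G + 0.114 B); pixel coordinates are 0-based with the origin
at the top-left, x rightward, y downward, positions referring to pixel
centers; frame indices are 0-based. Frames with no detection carry the last
position forward (so dropouts never inflate distances); `fillGaps()` can
replace runs of up to `maxGapFrames` missed frames by linear interpolation.
The frame rate comes from an explicit `fps` argument or the
`fpsOverride` detection setting — the TIFF container the package uses as its
lossless video format carries no rate metadata.

## Metrics

Calibration is isotropic: two image points a known distance apart give a
single cm/px scale. Per-ROI metrics follow three deliberate conventions:

* **membership by centroid** (the tracker's output), with boundary points
  belonging to the explicitly drawn ROI rather than the complement, and the
  first-declared ROI winning among overlaps;
* **step attribution to the earlier frame's zone**, which makes
  Σ<sub>ROI</sub> distance = total distance an exact identity, just as
  Σ<sub>ROI</sub> time = window duration holds because every frame
  contributes exactly one frame period;
* **mean speed = distance / time** per ROI (not the mean of instantaneous
  speeds); an unvisited ROI reports speed 0 with `defined = FALSE`.

Transitions use a debounce automaton: a zone change counts only when the new
label persists for `debounceFrames` consecutive frames (default 1, i.e. raw
changes). Whether a real LDB transition should require full-body rather than
centroid crossing is a matter of convention; centroid crossing is what a
centroid tracker can express, and the debounce parameter absorbs doorway
chatter. An optional teleport filter zeroes steps longer than `maxStepPx`,
guarding distance sums against residual detection glitches.

## Trajectory clustering

Trajectories are clipped to an analysis window (the early exploration
phase — e.g. the first 30 s — is where strategies differ most), then
*adjusted to the same area*: a per-axis affine map sends each arena
rectangle to the unit square. The map is not isotropic; for the square
arenas of standard OF setups this is immaterial, and it guarantees that
similar paths in different-sized arenas compare equal.

DTW is the classic unnormalized recurrence with Euclidean local cost, no
path-length division and no band by default (both configurable; a
Sakoe–Chiba corridor is available for long series). Sequences of unequal
length are compared as-is — warping absorbs the mismatch, so no resampling
is imposed before the distance.

k-means needs a vector space, so clustering operates on a 2-D metric MDS
embedding of the DTW matrix, and the silhouette is computed in that same
space — one consistent geometry for model selection, clustering and
display (the MDS scatter with centroids). The embedding uses classical
(Torgerson) scaling: it is the deterministic exact solution whenever the
dissimilarities are Euclidean-embeddable in the target dimension, which
makes the whole pipeline reproducible without an iteration seed; the
normalized residual stress is reported so poorly-embeddable matrices are
visible. k is scanned over 2…min(n−1, 10) with 10 seeded k-means restarts
per candidate; ties in mean silhouette go to the smaller k. Labels are
0-based ("cluster k-means 0, 1, 2, …"). Because a mean trajectory is not
defined in the DTW metric, each cluster's representative is its *medoid* —
the member minimizing the summed DTW distance to co-members.

## Angle clustering

The heading at each step is the direction of the displacement vector with
the image y-axis flipped, so 0° is rightward and counterclockwise is
positive. "Angle" could alternatively mean body-axis orientation from the
blob's ellipse fit; displacement heading is used because it is defined for
any tracker output and is the quantity that distinguishes circlers from
zig-zaggers. Displacements shorter than `minStepPx` have no reliable
direction and reuse the previous heading. The series is then *unwrapped*
(multiples of 360° added so successive differences lie in (−180°, 180°]):
DTW, smoothing and averaging all operate on the unwrapped scale, avoiding
the spurious 359° → 1° jumps of circular representations at the cost of
treating a full turn as 360° of displacement — appropriate here, since
cumulative turning is exactly what separates the archetypes.

Gaussian smoothing interprets "kernel size k" as a window of 2k + 1 samples
with σ = k/2 and reflect padding; the weights are normalized so constants
are fixed points, and larger k strictly calms the series (total variation
non-increasing over k = 1, 3, 10 on random series — a property the tests
assert).

Hierarchies are built by Lance–Williams agglomeration on the DTW matrix
with five linkages: Ward (minimizing the within-group variance increase),
single, complete, average and centroid. Ward's derivation assumes squared
Euclidean distances; applying its update to DTW dissimilarities follows
common practice and is validated against a coordinate-based oracle on
Euclidean inputs, but the heights should be read as relative, not as
variance decompositions. The flat clustering removes every merge above a
cutoff height and takes connected components of the remaining merge forest
— identical to the usual dendrogram cut for the monotone linkages, and
well-defined even under centroid inversions. The cutoff is expressed in raw
merge-height units, i.e. accumulated DTW degrees for angle series, where
values in the thousands are typical for 100-sample series (a constant
heading and a full 360° ramp of length 100 sit about 18 000 apart).

Each cluster is summarized by resampling members to the shortest member's
length and taking the pointwise mean and *population* SD (the cluster is
the whole population of interest, not a sample from one). Between-cluster
structure is displayed as the full accumulated DTW cost matrix between mean
profiles — mean curves rather than medoids, since the profile plot shows
means; a medoid-based comparison can be had by passing medoid members to
`clusterCostMatrix()` directly.

## The synthetic scene and what passing tests mean

The renderer draws a filled ellipse (default semi-axes 6 × 4 px, intensity
0) per arena on a uniform 255 background, following a scripted polyline at
constant speed, with i.i.d. Gaussian pixel noise (clipped to [0, 255]) and
a 2-s animal-free leader. Scenes use 1–4 disjoint rectangular arenas in
frames of 160 × 120 to 320 × 240 px at 5 fps — small enough that the full
render–track–cluster chain runs in seconds, large enough that the blob
spans ~75 px. Population fixtures plant cluster structure explicitly: four
trajectory archetypes (diagonal line, left arc, right arc, spiral) and
three angle archetypes (constant heading, 360° ramp, oscillation), each
member being archetype + seeded Gaussian noise (default trajectory noise
0.02 in unit-square units — visible jitter, small against the ~0.3
archetype separation).

Ground truth is analytic, so the tests can assert sub-pixel localization
(≤ 0.5 px per frame on noiseless scenes), ≤ 2 % distance recovery
(discretization only), ≥ 99 % detection at noise σ = θ/3, exact metric
conservation, DTW equal to exhaustive warping-path enumeration (all
sequence pairs up to length 6), all five linkages equal to brute-force
agglomeration, and perfect recovery of planted cluster structure.

What this does **not** establish: real recordings have shadows, reflections,
cable occlusions, non-elliptical posture, compression artifacts and camera
flicker, none of which the renderer emulates. Passing the suite shows the
*algorithms* are implemented correctly and the pipeline is internally
consistent; threshold, morphology radius and minimum blob area still need
per-setup adjustment on real footage, which is why they are exposed as
detection settings rather than constants.

## Numerical and degenerate-case choices

* Rendering, noise and k-means restarts are seeded; tracking itself is
  deterministic, so identical inputs give identical tracks, labels and
  files (byte-identical TIFFs).
* Closest-pair ties in agglomeration break toward the earliest pair in
  row-major order; silhouette ties in k selection break toward smaller k.
* A single-waypoint path renders a stationary blob; a single-sample track
  has distance 0; an all-undetected arena yields a warning and an empty
  track rather than an error.
* Heading is undefined until the first supra-threshold displacement;
  leading headings are backfilled from it, and an all-stationary trajectory
  is an error.
* `occupancyHeatmap()` closes the last bin on the right so arena-edge
  positions are counted.
* Problem sizes in the shipped tests (20 subjects, 80–100 samples per
  series, 6-point oracle matrices, 20 repetitions of the recovery
  experiment) were chosen so each stage's check is statistically meaningful
  while the whole suite stays interactive.

## Known limitations

* One animal per arena; identity across arenas is by containment, and
  multi-animal-per-arena scenes are out of scope.
* No pose estimation: the centroid is the only per-frame descriptor, so
  rearing/grooming and body-axis measures are unavailable.
* The native video format is multi-page TIFF; codec containers (AVI/MP4)
  should be converted on ingest (e.g. `ffmpeg -i in.mp4 out.tif`).
* Ward-on-DTW heights are heuristic (see above); for strictly Euclidean
  interpretability, cluster the MDS coordinates instead.
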