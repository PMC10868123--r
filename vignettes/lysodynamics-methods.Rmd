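---
title: "Quantifying lysosomal dynamics: models, parameters and validation"
author: "LysoDynamics package authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Quantifying lysosomal dynamics: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

LysoDynamics quantifies lysosome behaviour in calibrated live-cell
fluorescence time-lapse movies: how large the vesicles are and how much of
the cell they occupy, how long pairs of them stay in contact, how far they
travel, how they distribute around the nucleus, how bright functional dyes
are inside them, and whether two conditions differ in any of these per-cell
readouts. Every stage is validated against a bundled stochastic simulator
with known ground truth, so the package also serves as a test bed for the
measurement chain itself.

# The measurement pipeline

## Segmentation

Each frame is background-corrected by subtracting a grayscale morphological
opening (the rolling-ball family of estimators) with a square structuring
element of side `2 * rollingBallRadiusPx + 1`; the filter is an O(n)
separable running minimum/maximum, with edge-replicated borders, so the
radius is free. The default radius is 50 px, a scale far above any vesicle;
for the flat-background synthetic movies the matched configuration
(`simulationAnalysisConfig()`) uses 25 px, which is still an order of
magnitude above the rendered spot size.

The corrected frame is thresholded — Otsu's method by default, chosen
because it is parameter-free; a fixed threshold is available — and
connected components are labelled with 8-connectivity. Touching vesicles
merge into one component; no watershed splitting is attempted, because at
diffraction-limited resolution a split would be arbitrary. Objects are
gated to an equivalent circular diameter (the diameter of the circle with
the object's area) in the closed interval 0.1–2 µm, the operational
definition of a lysosome here.

## Tracking

Detections are linked frame to frame by minimum-total-distance one-to-one
assignment (Hungarian algorithm, implemented in C++) under a hard
displacement gate (`linkMaxDispUm`, default 1 µm/frame). There is no gap
closing: at a 2 s frame interval a missed frame is 2 s of unobserved
motion, and pretending otherwise would silently fabricate trajectory.

Merges receive special care because contacting vesicles routinely fuse
into one connected component. A track that loses the one-to-one
competition continues as a *shared* occupant of a neighbouring object
when, and only when, that is plausibly a segmentation merge: the two
tracks were within `mergeAttachUm` (default 0.8 µm, the scale of the
optical contact range) of each other in the previous frame, and the
candidate object's pixel area is at least 55% of the two tracks' combined
areas (sub-resolution spots fuse sub-additively). Both identities then persist through the merged interval and are
re-separated by the assignment step when the component splits. Without
this rule, every contact that merges optically would truncate its own
duration measurement.

## Contact events and censored durations

A tracked pair is *in contact* in a frame when their objects' pixel sets
overlap or are 8-adjacent within a configurable gap (`contactGapPx`,
default 1 px), or when the two tracks share one object (a merge). Maximal
contiguous runs of contact frames become events. Durations follow two
deliberate conventions:

* **Reported minimum duration** credits a contact seen in k consecutive
  frames with `k * dt` seconds, clipped at the censoring cap
  (`movieCapS`, 180 s): a contact spanning all 91 frames of a 3-minute
  movie is categorized as 180 s and flagged censored. Censoring is exact:
  an event is censored if and only if it reaches the final frame.
* **Stability** is judged on elapsed time: a contact existing at t = 0 is
  stable when `(last_frame - first_frame) * dt >= stableContactS` (10 s),
  i.e. it is still present at the fifth subsequent 2-s frame. Under a
  per-frame dissociation probability p this event has probability
  (1 − p)^5, which is the analytic anchor the validation suite uses. (A
  frame-count reading of the same rule — at least five frames of presence —
  would correspond to (1 − p)^4 and would be inconsistent with that
  anchor; the elapsed-time reading is also the natural reading of "stayed
  in contact for at least 10 s".)

The per-cell minimum-duration statistic follows the study design:
among events already existing at t = 0, five are sampled uniformly at
random (seeded, reproducible) and followed to dissociation or movie end.

Cross-channel contacts (lysosome–ER, lysosome–mitochondria) use strict
binary overlap with no adjacency tolerance, the fraction being the percent
of gated lysosomes overlapping the partner binary, averaged over frames.

## Motility, spatial distribution, intensity readouts

Motility uses only tracks of duration ≥ 60 s (31 frames at 2 s) and
reports the cumulative path length over the first 60 s window and the mean
speed over the whole track; both are emitted because "distance travelled"
and "average motility" are distinct quantities. Kymographs sample maximum
intensity across a perpendicular band along a polyline, one row per frame.

The perinuclear analysis computes an exact Euclidean distance transform of
the nucleus mask, scaled to µm, and classifies each vesicle by the field
value bilinearly interpolated at its centroid: strictly below 7 µm is
perinuclear, at or beyond is distal. Centroid evaluation (rather than
mask minimum) matches a per-object distance readout and is stable for
small vesicles; bilinear interpolation avoids 1-px quantization at the
cutoff.

Dye puncta (LysoTracker / Magic Red-style readouts) reuse the exact
segmentation chain and report puncta per µm² of cell mask and the mean of
per-object mean intensities (MFI) on the background-corrected frame.
Pixel-wise Pearson colocalization is computed over cell-mask pixels only,
which avoids background-driven inflation; object colocalization counts an
object as colocalized from a single overlapping pixel, appropriate for
point-like vesicles. PLA stacks are maximum-intensity projected, puncta
segmented with an independent (smaller) size gate, nuclei counted from the
DAPI projection with a minimum-area gate, and results expressed per
nucleus and as fold change against the control-group mean — so the control
group's mean fold change is identically 1.

## Statistics

The unit of analysis is the cell; organelle-level observations are
averaged per cell upstream, which prevents pseudo-replication. Two groups
are compared with the classic equal-variance two-tailed Student's t test
(a Welch option exists for robustness checks); three or more with one-way
ANOVA plus Tukey's HSD; one-sample comparisons (e.g. fold changes against
1) with the one-sample t. Summaries are mean ± SEM over cells with the
number of biological replicates carried for reporting. No correction is
applied across different metrics, only within a Tukey family.

# The simulator

`simulateCell()` generates movies with known ground truth. Vesicles
diffuse in an annulus between a circular nucleus and the cell boundary
(both reflecting), with an optional constant radial drift toward the
nucleus; the stationary radial density r·exp(−(r − r_n)·v/D) is used for
initial placement so recordings start at steady state. Tethering is
pairwise: an untethered pair whose surfaces come within `captureDistUm`
forms a tether with per-frame probability `pOn`; an existing tether
dissolves with probability `pOff` per frame, so lifetimes are geometric
with mean `dtS / pOff` seconds. Tethered partners (and, transitively,
connected clusters) move with the mean of their members' proposed
displacements, so clusters stay rigid and vesicles can hold several
tethers at once.

Two modelling details exist to keep the *optically measured* contact
duration aligned with the *latent* tether duration, which is what the
dwell-time analytics describe:

* On release, an isolated pair receives a kiss-and-run-style separation
  impulse (`releaseKickUm`, 0.5 µm) and is refractory until it leaves the
  capture range. Without this, a released pair lingers inside the optical
  contact range and immediately re-tethers, chaining what the imaging
  cannot help but see as one long contact; with it, dissociation is
  promptly visible. Inside clusters no kick is applied, so a release
  cannot rip neighbouring tethers apart.
* Reflections can stretch a tether past the capture range; the pair is
  contracted back onto it (the tether holds), and only irrecoverable
  geometry breaks it.

Rendering draws each vesicle as an isotropic Gaussian whose sigma combines
the particle radius with the PSF sigma (0.1 µm on 0.1 µm pixels, a
confocal-like point spread), on a constant photon background, then applies
Poisson shot noise and Gaussian read noise and rounds to 16-bit camera
counts. The default peak signal (800 photons over background 10, read
noise 3) corresponds to a bright, well-expressed marker with SNR ≈ 28;
detection fidelity is additionally verified at the ≥ 5 SNR regime the
validation suite requires.

Default conditions: 30 vesicles of radius 0.05–0.08 µm (sub-resolution,
so apposition rather than shape defines contact) in a 12 µm cell with a
3.5 µm nucleus; D = 0.02 µm²/s; capture distance 0.4 µm; pOn = 1
(diffusion-limited tethering — the stochastic element is dissociation);
pOff = 0.1 per frame; 91 frames at 2 s (180 s movies). The knockdown-like
contrast regime (`kdRegime()`) divides pOff by 10, halves diffusion,
doubles the perinuclear drift and halves the functional-dye brightness.

The matched analysis configuration (`simulationAnalysisConfig()`) sets the
contact gap tolerance to 3 px so the operational contact range (two
thresholded spot binaries within the gap) spans the capture range given
the rendered spot extent; with the package-default 1 px the optical range
would undershoot the tether geometry and fragment real contacts. This is
instrument matching fixed from geometry, not a fitted quantity.

## What the simulator does and does not emulate

It reproduces the statistical structure the measurement chain must cope
with: stochastic tethering with censoring at the movie end, merged binaries
during contacts, shot-noise-limited detection, crowding, radial bias. It
does not model directed microtubule transport (motility is diffusive plus
drift), photobleaching, z-motion, vesicle size heterogeneity beyond the
stated range, or ER/mitochondria morphology (static partner masks stand in
for cross-channel tests). Passing the validation suite therefore
demonstrates correctness of the measurement chain under these conditions,
not performance on any particular real dataset.

# Numerical choices and degenerate inputs

* Pixel coordinates are 0-based (row, col) between pixel centres; physical
  conversion happens once, at the metric layer.
* The size gate is a closed interval at both ends; 2.0 µm is retained.
* All-zero frames segment to zero objects (not an error); empty cell
  masks, empty nucleus masks, zero nuclei, zero variance in a correlation
  channel, and single-cell SEMs are signalled as errors or warnings, never
  silently defaulted.
* Calibration is never read from file metadata alone; explicit values are
  required and override metadata.
* The only randomness in the analysis path is the seeded contact sampling,
  so `runPipeline()` is a pure function of (movie, geometry, config).
* Validation problem sizes: the dwell-recovery study uses 50 simulated
  cells of 30 vesicles over 91 frames; the two-condition contrast uses 15
  cells per condition; statistical calibration uses 10⁴ null replicates.

# Known limitations

* Touching vesicles are measured as one object; sizes and counts are
  biased accordingly in crowded scenes (a documented property of
  connectivity-based segmentation without watershed).
* Contact durations are apposition durations: a brief diffusive encounter
  within the optical contact range is indistinguishable from a short
  tether, and a censored event only bounds its true duration from below.
* The tracker's merge bookkeeping resolves two-way merges well; transient
  three-way cluster fusions can still swap identities, which leaves pair
  bookkeeping intact but can mislabel which member is which.
* Per-frame Otsu thresholding assumes reasonably stationary illumination;
  bleaching correction is out of scope.
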