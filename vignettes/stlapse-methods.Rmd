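---
title: "Spectral time-lapse images and single-target tracking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral time-lapse images and single-target tracking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stlapse)
```

## The problem

Behavioural experiments in open environments are routinely recorded on video,
but a video is a poor summary: it must be watched in full, and a single still
frame shows *where* the animal was but not *when*. A spectral time-lapse
(STL) image solves this by painting the animal's position at every sampled
time point in a time-specific color and overlaying all of those detections on
one reference frame of the video. Early positions are red, later positions
sweep through the hue wheel, so one image shows the whole movement — the
sequence of places visited, the efficiency of the path, and (via the legend
bars) pauses. Because isolating the animal per frame is already most of a
tracker, the same machinery yields quantitative movement data: the x/y path,
total path length, duration, and smoothed instantaneous velocity and
acceleration — markerless, with no shape templates, for a single target.

## The pipeline

`runPipeline()` executes the stages in order; each is also exported on its
own.

**A — loading and sampling.** Video is decoded (uncompressed 24-bit AVI is
read natively; in-memory arrays are accepted for programmatic use), converted
to grey with the standard luma weights (0.299, 0.587, 0.114), normalized to
[0, 1], and subsampled: only every `sampling`-th frame is kept, because
cameras record at 24–30 fps while one position-per-second often suffices for
the image. The effective rate is reported as positions-per-second (pps)
alongside the source fps. `startFrame`/`endFrame` (0-based, inclusive, with a
1-based option for parity with the original MATLAB toolbox) window a longer
recording; sampling is anchored at `startFrame`. If the source was slowed or
sped (high-speed camera footage), `videospeed` rescales timestamps so every
downstream statistic is in real-world seconds: a 10×-slowed video has
`videospeed = 0.1` and a 30 fps, `sampling = 1` run of it yields 300 pps of
real time.

**B — target isolation.** Five calculations per frame: (1) subtract the
reference frame — the first or last frame, or a centered moving average
(window `refSmooth`, odd) when the background drifts; (2) Gaussian smoothing
with scale `smooth` (a sigma in pixels, kernel truncated at 3 sigma,
symmetric reflection at the borders so edges get no dark halo) — calibrate
sigma to the animal's apparent size; (3) polarity normalization, flipping the
sign so the target is always positive regardless of whether it is darker or
lighter than the background, clipping opposite-sign residuals to zero;
(4) masking: a static mask image for fixed occluders, and `cleanWhite`, which
zeroes pixels brighter than `white` in the *source* frame to suppress
burnt-in timestamps; (5) trimming frames from the start and end in which the
target is absent.

**C–E — rendering.** Each retained frame k of n gets the fully saturated hue
`(k/(n−1))·cycles mod 1`; pixels of its difference map above `threshMask` are
painted in that color with alpha proportional to intensity (normalized per
frame). The colorized frames are averaged — alpha-weighted, so a location
visited once among n frames keeps its own hue at 1/n intensity — and the
average's saturation is amplified (`oversatCol`) to restore visibility. The
color layer is then alpha-blended over the (optionally saturation-boosted,
`oversatRef`) reference; pixels never visited equal the boosted reference
exactly. Three legend bars stack at the bottom left: a white bar spanning
`timeBar` real seconds, a black/white strip marking frames whose thresholded
target region overlaps a temporal neighbour by more than `threshAdjac`
(pauses), and the time-colormap strip; all three use the same
pixels-per-frame scale so they are mutually comparable.

**F — path analysis.** At `pathSampling` pps (usually finer than the STL
image), each difference map is binarized at `threshTrim`, connected
components are labelled (8-connectivity), and the centroid of the largest
component is the target position — provided its area reaches `areamin`,
which re-determines the start and end of the path. Interior missed
detections are linearly interpolated; leading and trailing ones are dropped.
With `px2m` set, coordinates and path length are in meters.

**G — kinematics.** Speeds are chord distances over time steps, placed at
interval midpoints; accelerations are first differences of (smoothed) speeds
at midpoints of midpoints. Both series are smoothed with a centered weighted
moving average (`velSmooth`), ends renormalized.

## Parameters that matter

| setting | unit / range | default | rationale |
|---|---|---|---|
| `sampling` | frames | 30 | 30 fps video → 1 pps, the typical image density |
| `smooth` | px (sigma) | 2 | suits a target of radius ~5–10 px; scale with the animal |
| `threshMask` | [0, 1] intensity | 0.05 | above sensor noise, far below a real target's contrast |
| `threshTrim` | [0, 1] intensity | 0.1 | a region must peak above this to count as the target |
| `white` | [0, 1] intensity | 0.95 | overlays are near-saturated white |
| `cmap` | cycles | 1 | one unambiguous sweep of the hue wheel |
| `oversatCol` | factor ≥ 0 | 2 | counteracts the 1/n dilution of averaging |
| `threshAdjac` | [0, 1] fraction | 0.5 | overlap-of-min above ½ reads as a pause |
| `pathSampling` | pps | 6 | a workable rate for arena-scale locomotion |
| `areamin` | px² | 20 | rejects specks; well below a radius-6 target's ~110 px |
| `velSmooth` | weights | (¼, ½, ¼) | the minimal binomial kernel; halves jitter variance without flattening real events |

## Operationalizations and numerical choices

Several steps are described only qualitatively in the literature on this
family of methods; the package fixes them as follows.

* **Trim criterion.** A frame is target-containing iff the binary map
  `diff > threshMask` has a connected component of area ≥ an area floor
  (`ceil(pi * smooth^2)`, the smoothing kernel's core footprint) whose peak
  intensity exceeds `threshTrim`. This keeps the two thresholds in the roles
  their names suggest and makes the retained count monotone in `threshTrim`.
  Trimming removes frames only from the ends; interior gaps are kept.
* **Polarity auto-detection** uses the sign of the extreme value of the
  summed difference stack. This is reliable when the reference frame is
  target-free (the usual case: recordings start before the animal enters).
  When the reference itself contains the animal, the static "ghost" at the
  reference position dominates the sum and the heuristic can invert — set
  `polarity` explicitly (or use a moving-average reference) in that case.
* **Overlap statistic** is intersection-over-min, not intersection-over-
  union: if a small region sits inside a larger one the frames clearly
  overlap, and IoU would understate that.
* **Centroid** is the unweighted (binary) center of mass of the largest
  component; an intensity-weighted variant is available
  (`detectTarget(weighted = TRUE)`). Equal-area ties break by total
  intensity, then scan order. Coordinates are 0-based pixel centers, origin
  top-left, x rightward, y downward.
* **Averaging/compositing semantics.** Colorized frames carry straight alpha
  proportional to normalized intensity; averaging premultiplies, so the
  composite `premult + (1 − meanAlpha) · reference` preserves untouched
  pixels bit-exactly (a tested invariant).
* **Boundary handling** for convolution is symmetric reflection; kernels are
  normalized to sum 1, so constant regions are fixed points.
* **Degenerate inputs.** A single retained frame gets hue 0; an all-zero
  difference stack defaults to `target_darker`; a track with one sample has
  zero path length; smoothing weights must be odd-length, nonnegative and
  sum to 1 or a config error is raised.

## What the synthetic generator emulates — and what it does not

`generateFixture()` renders the stated world of a behavioural recording: a
static grey background (optionally drifting linearly in brightness), one
compact target darker or lighter than the background with anti-aliased
(sub-pixel coverage) edges so sub-pixel centroid recovery is meaningful,
parametric trajectories (stationary, linear, circular, piecewise with
pauses), empty lead/tail frames before entry and after exit, optional
additive Gaussian pixel noise (applied after compositing, clipped to [0, 1]),
and an optional saturated overlay rectangle standing in for a burnt-in
timestamp. Generation is deterministic given the seed, and the exact
per-frame center is returned as ground truth.

It deliberately does **not** emulate: deformable or rotating bodies, shadows
and specular highlights, occlusions, interlacing or compression artifacts,
lens distortion, or abrupt global illumination changes. A green test
therefore establishes that the algorithmic chain — isolation, thresholding,
labelling, centroid, differencing — is correct and numerically tight on
well-posed input; it does not certify performance on footage whose
difficulties are photometric. Those failure modes are exactly the ones the
configuration knobs (masking, moving-average reference, explicit polarity,
`areamin`) exist to manage.

One quantization effect deserves note: the binary centroid of a thresholded
disk moves in slightly uneven sub-pixel steps as the disk crosses the pixel
grid. The resulting jitter is negligible for positions and path lengths, but
double differentiation amplifies it quadratically with the sampling rate, so
recovered accelerations on *noise-free* fixtures still carry a small
rate-dependent floor. The kinematics acceptance fixture therefore uses
constant-velocity motion at an integer number of pixels per sample (18 px/s
at 6 pps), which isolates the differencing/smoothing chain from grid
quantization; trajectory-recovery accuracy under non-integer motion is
covered separately by the RMSE criterion, and the weighted-centroid option
reduces the jitter where second derivatives matter.

## Known limitations

Single target only; no occlusion recovery (a fully occluded target is an
interior gap, linearly interpolated); no lens-distortion correction, so path
lengths from wide-angle footage inherit that bias; only uncompressed 24-bit
AVI is decoded natively (convert other containers externally, or pass
decoded arrays); the polarity heuristic's reference-frame caveat above.
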