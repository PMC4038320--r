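#' @import methods
NULL

#' FrameSequence: sampled grey-scale frames with timing metadata
#'
#' Ordered grey-scale frames decoded from a video, stored as an
#' \code{H x W x N} array with values in \code{[0, 1]}, together with the
#' original (0-based) frame numbers, real-world timestamps in seconds, the
#' acquisition rate (\code{fpsSource}) and the effective positions-per-second
#' after sub-sampling (\code{pps}).  \code{videospeed} is the real-time
#' multiplier of the source video (0.1 for a recording slowed 10x from a
#' high-speed camera), already folded into \code{timestamps} and \code{pps}.
#'
#' @slot frames numeric array, \code{H x W x N}, values in \code{[0, 1]}.
#' @slot frameIndices integer, 0-based frame numbers in the source video.
#' @slot timestamps numeric, strictly increasing real-world seconds;
#'   \code{frameIndices / fpsSource * videospeed}.
#' @slot fpsSource numeric, frames-per-second of acquisition.
#' @slot pps numeric, positions-per-second after sampling,
#'   \code{fpsSource / sampling / videospeed}.
#' @slot videospeed numeric, real-time multiplier.
#'
#' @seealso [loadVideo()]
#' @export
setClass("FrameSequence",
  representation(
    frames = "array",
    frameIndices = "integer",
    timestamps = "numeric",
    fpsSource = "numeric",
    pps = "numeric",
    videospeed = "numeric"
  )
)

setValidity("FrameSequence", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "'frames' must be an H x W x N array")
  else {
    n <- d[3L]
    if (length(object@frameIndices) != n)
      msg <- c(msg, "length(frameIndices) must equal number of frames")
    if (length(object@timestamps) != n)
      msg <- c(msg, "length(timestamps) must equal number of frames")
    if (n > 1L && any(diff(object@timestamps) <= 0))
      msg <- c(msg, "timestamps must be strictly increasing")
  }
  rng <- range(object@frames)
  if (rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9)
    msg <- c(msg, "frame intensities must lie in [0, 1]")
  if (object@fpsSource <= 0) msg <- c(msg, "fpsSource must be positive")
  if (object@pps <= 0) msg <- c(msg, "pps must be positive")
  if (object@videospeed <= 0) msg <- c(msg, "videospeed must be positive")
  if (length(msg)) msg else TRUE
})

#' ReferenceSpec: how the reference frame is defined
#'
#' The reference is subtracted from every sampled frame to isolate the moving
#' target.  It is either a fixed frame (\code{"first"} or \code{"last"}) or a
#' per-frame \code{"moving_average"} over a centered window, which is useful
#' when the background changes slowly over time (lighting, bedding).
#'
#' @slot mode character, one of \code{"first"}, \code{"last"},
#'   \code{"moving_average"}.
#' @slot window integer, window width in frames for the moving average
#'   (odd, so the window is centered; truncated at the sequence ends).
#'
#' @seealso [computeReference()]
#' @export
setClass("ReferenceSpec",
  representation(mode = "character", window = "integer")
)

setValidity("ReferenceSpec", function(object) {
  msg <- character()
  if (!object@mode %in% c("first", "last", "moving_average"))
    msg <- c(msg, "mode must be 'first', 'last' or 'moving_average'")
  if (object@window < 1L) msg <- c(msg, "window must be >= 1")
  if (object@mode == "moving_average" && object@window %% 2L == 0L)
    msg <- c(msg, "window must be odd for a centered moving average")
  if (length(msg)) msg else TRUE
})

#' PreprocessConfig: settings for target isolation
#'
#' All intensity thresholds are on the normalized \code{[0, 1]} scale.
#'
#' @slot smoothSigma numeric, Gaussian kernel scale in pixels (kernel
#'   truncated at 3 sigma); 0 disables smoothing.  Calibrate to the apparent
#'   size of the animal in pixels.
#' @slot doMask logical, apply a pre-made static mask.
#' @slot maskPath character, path to the mask image (PNG; nonzero = keep),
#'   or \code{NA}.
#' @slot cleanWhite logical, dynamically zero pixels brighter than
#'   \code{white} in the source frame (hard-coded timestamps and overlays).
#' @slot white numeric in \code{[0, 1]}, brightness threshold for
#'   \code{cleanWhite}.
#' @slot threshMask numeric in \code{[0, 1]}, intensity threshold applied to
#'   difference maps when building target masks.
#' @slot threshTrim numeric in \code{[0, 1]}, peak-intensity threshold a
#'   connected region must exceed for its frame to count as
#'   target-containing.
#' @slot disableTrim logical, keep all frames regardless of target presence.
#' @slot polarity character, \code{"auto"}, \code{"target_darker"} or
#'   \code{"target_lighter"}.
#'
#' @seealso [preprocess()]
#' @export
setClass("PreprocessConfig",
  representation(
    smoothSigma = "numeric",
    doMask = "logical",
    maskPath = "character",
    cleanWhite = "logical",
    white = "numeric",
    threshMask = "numeric",
    threshTrim = "numeric",
    disableTrim = "logical",
    polarity = "character"
  )
)

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  inUnit <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
  if (object@smoothSigma < 0) msg <- c(msg, "smoothSigma must be >= 0")
  if (!inUnit(object@white)) msg <- c(msg, "white must be in [0, 1]")
  if (!inUnit(object@threshMask)) msg <- c(msg, "threshMask must be in [0, 1]")
  if (!inUnit(object@threshTrim)) msg <- c(msg, "threshTrim must be in [0, 1]")
  if (!object@polarity %in% c("auto", "target_darker", "target_lighter"))
    msg <- c(msg, "polarity must be 'auto', 'target_darker' or 'target_lighter'")
  if (object@doMask && is.na(object@maskPath))
    msg <- c(msg, "doMask is set but maskPath is missing")
  if (length(msg)) msg else TRUE
})

#' DifferenceStack: per-frame target-isolated intensity maps
#'
#' The result of preprocessing a [FrameSequence]: for every sampled frame a
#' nonnegative difference map in which the moving target is bright and the
#' static background is (near) zero, plus a retained/trimmed flag per frame.
#' Trimming removes frames from the start and end of the video in which the
#' target is absent, so \code{retained} always marks one contiguous interval.
#'
#' @slot diffs numeric array \code{H x W x N}, nonnegative.
#' @slot retained logical, length N.
#' @slot timestamps numeric, length N, inherited real-world seconds.
#' @slot polarity character, \code{"target_darker"} or \code{"target_lighter"}.
#' @slot pps numeric, positions-per-second of the stack.
#'
#' @seealso [preprocess()], [trimFrames()]
#' @export
setClass("DifferenceStack",
  representation(
    diffs = "array",
    retained = "logical",
    timestamps = "numeric",
    polarity = "character",
    pps = "numeric"
  )
)

setValidity("DifferenceStack", function(object) {
  msg <- character()
  d <- dim(object@diffs)
  if (length(d) != 3L)
    msg <- c(msg, "'diffs' must be an H x W x N array")
  else {
    n <- d[3L]
    if (length(object@retained) != n)
      msg <- c(msg, "length(retained) must equal number of frames")
    if (length(object@timestamps) != n)
      msg <- c(msg, "length(timestamps) must equal number of frames")
  }
  if (min(object@diffs) < -1e-9)
    msg <- c(msg, "difference maps must be nonnegative")
  if (!object@polarity %in% c("target_darker", "target_lighter"))
    msg <- c(msg, "polarity must be 'target_darker' or 'target_lighter'")
  r <- object@retained
  if (any(r)) {
    span <- range(which(r))
    if (!all(r[span[1L]:span[2L]]))
      msg <- c(msg, "retained frames must form one contiguous interval")
  }
  if (length(msg)) msg else TRUE
})

#' TimeColormap: mapping from retained-frame index to an RGB color
#'
#' Frame \code{k} (0-based) of \code{n} retained frames receives the fully
#' saturated, full-value hue at \code{(k / (n - 1)) * cycles mod 1}; with
#' \code{cycles = 2} the hue wheel is traversed twice across the video.
#'
#' @slot n integer, number of retained frames.
#' @slot cycles numeric, number of color-wheel cycles (typically 1 or 2).
#' @slot colors numeric matrix \code{n x 3}, RGB in \code{[0, 1]}.
#'
#' @seealso [buildTimeColormap()]
#' @export
setClass("TimeColormap",
  representation(n = "integer", cycles = "numeric", colors = "matrix")
)

setValidity("TimeColormap", function(object) {
  msg <- character()
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (object@cycles <= 0) msg <- c(msg, "cycles must be > 0")
  if (!is.numeric(object@colors) || ncol(object@colors) != 3L ||
      nrow(object@colors) != object@n)
    msg <- c(msg, "colors must be an n x 3 numeric matrix")
  else {
    if (min(object@colors) < -1e-9 || max(object@colors) > 1 + 1e-9)
      msg <- c(msg, "colors must lie in [0, 1]")
    # fully saturated, full value: each hue has max channel 1 and min 0
    if (max(abs(apply(object@colors, 1L, max) - 1)) > 1e-9 ||
        max(abs(apply(object@colors, 1L, min))) > 1e-9)
      msg <- c(msg, "colors must be fully saturated and full-value")
  }
  if (length(msg)) msg else TRUE
})

#' STLImage: composite spectral time-lapse image with legend metadata
#'
#' The rendered STL image: time-colored target positions composited over the
#' (saturation-boosted) reference frame, with three legend bars at the bottom
#' left: a fixed-real-time bar, a per-frame black/white overlap strip (white
#' marks frames whose target region strongly overlapped a neighbour,
#' i.e. pauses), and the time-to-color strip.
#'
#' @slot pixels numeric array \code{H x W x 3}, RGB in \code{[0, 1]}.
#' @slot barSize integer, legend bar height in pixels.
#' @slot pxPerFrame integer, legend strip pixels allotted per retained frame.
#' @slot timeBarPx integer, length of the real-time bar in pixels.
#' @slot overlapFlags logical, per retained frame.
#' @slot colors numeric matrix, the time colormap used (\code{n x 3}).
#'
#' @seealso [composeSTL()]
#' @export
setClass("STLImage",
  representation(
    pixels = "array",
    barSize = "integer",
    pxPerFrame = "integer",
    timeBarPx = "integer",
    overlapFlags = "logical",
    colors = "matrix"
  )
)

setValidity("STLImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3L] != 3L)
    msg <- c(msg, "'pixels' must be an H x W x 3 array")
  if (min(object@pixels) < -1e-9 || max(object@pixels) > 1 + 1e-9)
    msg <- c(msg, "pixel values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' PathTrack: time-ordered target positions with path statistics
#'
#' Positions of the target at regular intervals, as (t, x, y) samples.
#' Coordinates use the image convention: origin at the top-left pixel center,
#' x rightward, y downward, 0-based.  If a pixels-to-meters factor
#' (\code{px2m}) is supplied the coordinates and path length are in meters.
#'
#' @slot samples data.frame with columns \code{t} (seconds), \code{x},
#'   \code{y}; \code{t} strictly increasing.
#' @slot units character, \code{"pixels"} or \code{"meters"}.
#' @slot px2m numeric, meters per pixel, or \code{NA} if unset.
#' @slot pathLength numeric, sum of Euclidean distances between consecutive
#'   samples, in \code{units}.
#' @slot duration numeric, \code{t_last - t_first} in seconds.
#' @slot pps numeric, sampling rate used for path extraction.
#'
#' @seealso [extractPath()]
#' @export
setClass("PathTrack",
  representation(
    samples = "data.frame",
    units = "character",
    px2m = "numeric",
    pathLength = "numeric",
    duration = "numeric",
    pps = "numeric"
  )
)

setValidity("PathTrack", function(object) {
  msg <- character()
  s <- object@samples
  if (!all(c("t", "x", "y") %in% names(s)))
    msg <- c(msg, "samples must have columns t, x, y")
  else {
    if (nrow(s) > 1L && any(diff(s$t) <= 0))
      msg <- c(msg, "sample times must be strictly increasing")
    if (any(!is.finite(s$x)) || any(!is.finite(s$y)))
      msg <- c(msg, "coordinates must be finite")
  }
  if (!object@units %in% c("pixels", "meters"))
    msg <- c(msg, "units must be 'pixels' or 'meters'")
  if (object@pathLength < 0) msg <- c(msg, "pathLength must be >= 0")
  if (length(msg)) msg else TRUE
})

#' KinematicsSeries: instantaneous velocity and acceleration
#'
#' Velocity values sit at the midpoints of consecutive track samples
#' (\code{n - 1} values for \code{n} samples); accelerations at the midpoints
#' of consecutive velocity midpoints (\code{n - 2} values).  Smoothing, when
#' applied, is a centered weighted moving average whose weights sum to 1.
#'
#' @slot tVel numeric, velocity timestamps (seconds, midpoint convention).
#' @slot velocity numeric, units/s, nonnegative.
#' @slot tAcc numeric, acceleration timestamps.
#' @slot acceleration numeric, units/s^2 (may be negative or empty).
#' @slot weights numeric, the smoothing weights applied (length 1 weight 1
#'   means unsmoothed).
#' @slot units character, spatial units of the source track.
#'
#' @seealso [velocitySeries()], [accelerationSeries()], [computeKinematics()]
#' @export
setClass("KinematicsSeries",
  representation(
    tVel = "numeric",
    velocity = "numeric",
    tAcc = "numeric",
    acceleration = "numeric",
    weights = "numeric",
    units = "character"
  )
)

setValidity("KinematicsSeries", function(object) {
  msg <- character()
  if (length(object@tVel) != length(object@velocity))
    msg <- c(msg, "tVel and velocity must have equal length")
  if (length(object@tAcc) != length(object@acceleration))
    msg <- c(msg, "tAcc and acceleration must have equal length")
  if (length(object@velocity) && min(object@velocity) < -1e-12)
    msg <- c(msg, "velocity must be nonnegative")
  if (abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "smoothing weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' FixtureSpec: a synthetic behavioural video with known ground truth
#'
#' Describes a deterministic synthetic video: a single compact target (darker
#' or lighter than a static grey background) moving along a parametric
#' trajectory, with optional empty lead/tail frames, additive Gaussian pixel
#' noise, slow background drift and a bright hard-coded overlay rectangle
#' emulating a burnt-in timestamp.
#'
#' @slot size integer length 2, \code{c(H, W)} in pixels.
#' @slot fps numeric, frames per second.
#' @slot nFrames integer, total frame count.
#' @slot background numeric in \code{[0, 1]}, base intensity.
#' @slot backgroundDrift numeric, additive intensity drift per second.
#' @slot blobRadius numeric, target radius in pixels.
#' @slot blobAmplitude numeric, signed intensity offset of the target
#'   (negative = darker than background).
#' @slot blobProfile character, \code{"disk"} (anti-aliased hard disk) or
#'   \code{"gaussian"}.
#' @slot trajectory list, \code{type} plus parameters; see
#'   [generateFixture()].
#' @slot leadEmpty,tailEmpty integer, frames with no target at the start/end.
#' @slot noiseSd numeric, additive Gaussian pixel noise sd.
#' @slot overlayBox list or NULL-length list; \code{x}, \code{y}, \code{w},
#'   \code{h} (0-based, pixels) and \code{intensity}.
#' @slot seed integer, RNG seed; same seed gives bit-identical frames.
#'
#' @seealso [generateFixture()]
#' @export
setClass("FixtureSpec",
  representation(
    size = "integer",
    fps = "numeric",
    nFrames = "integer",
    background = "numeric",
    backgroundDrift = "numeric",
    blobRadius = "numeric",
    blobAmplitude = "numeric",
    blobProfile = "character",
    trajectory = "list",
    leadEmpty = "integer",
    tailEmpty = "integer",
    noiseSd = "numeric",
    overlayBox = "list",
    seed = "integer"
  )
)

setValidity("FixtureSpec", function(object) {
  msg <- character()
  if (length(object@size) != 2L || any(object@size < 8L))
    msg <- c(msg, "size must be c(H, W) with both >= 8")
  if (object@fps <= 0) msg <- c(msg, "fps must be positive")
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@background < 0 || object@background > 1)
    msg <- c(msg, "background must be in [0, 1]")
  if (object@blobRadius <= 0) msg <- c(msg, "blobRadius must be positive")
  if (!object@blobProfile %in% c("disk", "gaussian"))
    msg <- c(msg, "blobProfile must be 'disk' or 'gaussian'")
  if (is.null(object@trajectory$type))
    msg <- c(msg, "trajectory must have a 'type'")
  if (object@leadEmpty < 0L || object@tailEmpty < 0L)
    msg <- c(msg, "leadEmpty/tailEmpty must be >= 0")
  if (object@leadEmpty + object@tailEmpty >= object@nFrames)
    msg <- c(msg, "leadEmpty + tailEmpty must leave at least one target frame")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})
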