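#' @describeIn FrameSequence number of sampled frames
#' @param x object
#' @export
setMethod("nframes", "FrameSequence", function(x) dim(x@frames)[3L])

#' @describeIn DifferenceStack number of frames in the stack
#' @param x object
#' @export
setMethod("nframes", "DifferenceStack", function(x) dim(x@diffs)[3L])

#' @describeIn FrameSequence frame array
#' @export
setMethod("frames", "FrameSequence", function(x) x@frames)

#' @describeIn DifferenceStack difference-map array
#' @export
setMethod("frames", "DifferenceStack", function(x) x@diffs)

#' @describeIn FrameSequence timestamps in real-world seconds
#' @export
setMethod("timestamps", "FrameSequence", function(x) x@timestamps)

#' @describeIn DifferenceStack timestamps in real-world seconds
#' @export
setMethod("timestamps", "DifferenceStack", function(x) x@timestamps)

#' @describeIn FrameSequence positions-per-second after sampling
#' @export
setMethod("pps", "FrameSequence", function(x) x@pps)

#' @describeIn DifferenceStack positions-per-second of the stack
#' @export
setMethod("pps", "DifferenceStack", function(x) x@pps)

#' @describeIn PathTrack sampling rate used for path extraction
#' @export
setMethod("pps", "PathTrack", function(x) x@pps)

#' @describeIn FrameSequence acquisition fps of the source video
#' @export
setMethod("fpsSource", "FrameSequence", function(x) x@fpsSource)

#' @describeIn DifferenceStack retained flags after trimming
#' @export
setMethod("retained", "DifferenceStack", function(x) x@retained)

#' @describeIn DifferenceStack detected target polarity
#' @export
setMethod("polarity", "DifferenceStack", function(x) x@polarity)

#' @describeIn PathTrack samples as data.frame(t, x, y)
#' @export
setMethod("trackSamples", "PathTrack", function(x) x@samples)

#' @describeIn PathTrack total path length in the track's units
#' @export
setMethod("pathLength", "PathTrack", function(x) x@pathLength)

#' @describeIn PathTrack duration in seconds
#' @export
setMethod("trackDuration", "PathTrack", function(x) x@duration)

#' @describeIn KinematicsSeries velocity values (units/s)
#' @export
setMethod("velocity", "KinematicsSeries", function(x) x@velocity)

#' @describeIn KinematicsSeries acceleration values (units/s^2)
#' @export
setMethod("acceleration", "KinematicsSeries", function(x) x@acceleration)

#' @describeIn STLImage RGB pixel array
#' @export
setMethod("pixels", "STLImage", function(x) x@pixels)

#' @describeIn TimeColormap RGB colors, one row per retained frame
#' @export
setMethod("frameColors", "TimeColormap", function(x) x@colors)

#' @describeIn STLImage colormap used for the legend strip
#' @export
setMethod("frameColors", "STLImage", function(x) x@colors)

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "FrameSequence: %d frames of %d x %d px\n  fps (source): %g  pps: %g  videospeed: %g\n  time span: %.3f..%.3f s\n",
    d[3L], d[1L], d[2L], object@fpsSource, object@pps, object@videospeed,
    object@timestamps[1L], object@timestamps[d[3L]]
  ))
})

setMethod("show", "DifferenceStack", function(object) {
  d <- dim(object@diffs)
  r <- which(object@retained)
  span <- if (length(r)) sprintf("%d..%d (of %d)", min(r), max(r), d[3L])
          else sprintf("none (of %d)", d[3L])
  cat(sprintf(
    "DifferenceStack: %d frames of %d x %d px\n  polarity: %s  pps: %g\n  retained: %s\n",
    d[3L], d[1L], d[2L], object@polarity, object@pps, span
  ))
})

setMethod("show", "TimeColormap", function(object) {
  cat(sprintf("TimeColormap: %d frames, %g color cycle(s)\n",
              object@n, object@cycles))
})

setMethod("show", "STLImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "STLImage: %d x %d px, %d retained frames\n  legend: barSize %d px, time bar %d px, %d/%d overlap flags set\n",
    d[1L], d[2L], nrow(object@colors), object@barSize, object@timeBarPx,
    sum(object@overlapFlags), length(object@overlapFlags)
  ))
})

setMethod("show", "PathTrack", function(object) {
  u <- if (object@units == "meters") "m" else "px"
  cat(sprintf(
    "PathTrack: %d samples at %g pps\n  path length: %.3f %s  duration: %.3f s\n",
    nrow(object@samples), object@pps, object@pathLength, u, object@duration
  ))
})

setMethod("show", "KinematicsSeries", function(object) {
  cat(sprintf(
    "KinematicsSeries: %d velocity / %d acceleration values (%s)\n  smoothing weights: %s\n",
    length(object@velocity), length(object@acceleration), object@units,
    paste(signif(object@weights, 3L), collapse = ", ")
  ))
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf(
    "FixtureSpec: %d frames of %d x %d px at %g fps\n  trajectory: %s  blob r=%g amp=%+g (%s)\n  lead/tail empty: %d/%d  noise sd: %g  seed: %d\n",
    object@nFrames, object@size[1L], object@size[2L], object@fps,
    object@trajectory$type, object@blobRadius, object@blobAmplitude,
    object@blobProfile, object@leadEmpty, object@tailEmpty, object@noiseSd,
    object@seed
  ))
})
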