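#' Number of frames
#' @param x a [FrameSequence] or [DifferenceStack]
#' @return integer frame count
#' @export
setGeneric("nframes", function(x) standardGeneric("nframes"))

#' Frame data as an H x W x N array
#' @param x a [FrameSequence] or [DifferenceStack]
#' @return numeric array
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Real-world timestamps in seconds
#' @param x a [FrameSequence], [DifferenceStack] or [KinematicsSeries]
#' @return numeric vector
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' Positions-per-second of a sampled object
#' @param x a [FrameSequence], [DifferenceStack] or [PathTrack]
#' @return numeric scalar
#' @export
setGeneric("pps", function(x) standardGeneric("pps"))

#' Acquisition frame rate of the source video
#' @param x a [FrameSequence]
#' @return numeric scalar
#' @export
setGeneric("fpsSource", function(x) standardGeneric("fpsSource"))

#' Retained-frame flags after trimming
#' @param x a [DifferenceStack]
#' @return logical vector, one contiguous TRUE interval
#' @export
setGeneric("retained", function(x) standardGeneric("retained"))

#' Target polarity relative to the background
#' @param x a [DifferenceStack]
#' @return \code{"target_darker"} or \code{"target_lighter"}
#' @export
setGeneric("polarity", function(x) standardGeneric("polarity"))

#' Track samples as a data.frame of (t, x, y)
#' @param x a [PathTrack]
#' @return data.frame
#' @export
setGeneric("trackSamples", function(x) standardGeneric("trackSamples"))

#' Total path length
#' @param x a [PathTrack]
#' @return numeric scalar in the track's units
#' @export
setGeneric("pathLength", function(x) standardGeneric("pathLength"))

#' Track duration in seconds
#' @param x a [PathTrack]
#' @return numeric scalar
#' @export
setGeneric("trackDuration", function(x) standardGeneric("trackDuration"))

#' Instantaneous velocity values
#' @param x a [KinematicsSeries]
#' @return numeric vector, units/s
#' @export
setGeneric("velocity", function(x) standardGeneric("velocity"))

#' Instantaneous acceleration values
#' @param x a [KinematicsSeries]
#' @return numeric vector, units/s^2
#' @export
setGeneric("acceleration", function(x) standardGeneric("acceleration"))

#' Pixel data of a rendered image
#' @param x an [STLImage]
#' @return numeric H x W x 3 array in [0, 1]
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Frame colors of a time colormap
#' @param x a [TimeColormap] or [STLImage]
#' @return numeric n x 3 matrix, RGB in [0, 1]
#' @export
setGeneric("frameColors", function(x) standardGeneric("frameColors"))
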