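#' Load a video as a sampled grey-scale frame sequence
#'
#' Decodes a video and keeps every \code{sampling}-th frame within
#' \code{[startFrame, endFrame]} (0-based, inclusive on both ends; sampling is
#' anchored at \code{startFrame}).  Frames are converted to grey-scale with
#' the standard luma weighting (0.299 R + 0.587 G + 0.114 B) and normalized
#' to \code{[0, 1]}.  Video is often acquired at a higher rate than the
#' analysis needs, e.g. 30 fps when one position-per-second suffices, so
#' \code{sampling = 30} reduces such a video to 1 pps.
#'
#' If the source was slowed or sped relative to real time (high-speed camera
#' footage), pass \code{videospeed} (0.1 for a 10x-slowed video): timestamps
#' are \code{frameIndex / fps * videospeed}, so all downstream statistics are
#' in real-world seconds, and \code{pps = fps / (sampling * videospeed)}.
#'
#' @param video path to an uncompressed 24-bit AVI file, or an in-memory
#'   numeric \code{H x W x N} array of grey frames in \code{[0, 1]} (then
#'   \code{fps} is required).
#' @param sampling positive integer, keep every \code{sampling}-th frame.
#' @param startFrame,endFrame optional 0-based frame range, inclusive.  Set
#'   \code{oneBased = TRUE} to interpret them 1-based for parity with the
#'   original MATLAB toolbox.
#' @param videospeed positive real-time multiplier of the source video.
#' @param fps frames-per-second, required for array input, ignored for AVI
#'   input (read from the header).
#' @param oneBased logical, interpret \code{startFrame}/\code{endFrame} as
#'   1-based indices.
#' @return a [FrameSequence].
#' @examples
#' fx <- generateFixture(fixtureSpec(nFrames = 30, size = c(48L, 64L)))
#' seq <- loadVideo(fx$frames, sampling = 10, fps = fx$fps)
#' nframes(seq)  # 3
#' @export
loadVideo <- function(video, sampling = 1L, startFrame = NULL,
                      endFrame = NULL, videospeed = 1,
                      fps = NULL, oneBased = FALSE) {
  sampling <- as.integer(sampling)
  if (is.na(sampling) || sampling < 1L) stop("sampling must be a positive integer")
  if (videospeed <= 0) stop("videospeed must be positive")

  if (is.character(video)) {
    avi <- parseAVI(video)
    nTotal <- length(avi$frameOffsets)
    fps <- avi$fps
    fetch <- function(k1) decodeAVIFrame(avi, k1)   # k1 is 1-based
  } else if (is.array(video) && length(dim(video)) == 3L) {
    if (is.null(fps)) stop("fps is required for in-memory frame input")
    nTotal <- dim(video)[3L]
    fetch <- function(k1) video[, , k1]
  } else stop("video must be a file path or an H x W x N array")
  if (nTotal < 1L) stop("decode error: video contains no frames")

  off <- if (isTRUE(oneBased)) 1L else 0L
  s0 <- if (is.null(startFrame)) 0L else as.integer(startFrame) - off
  e0 <- if (is.null(endFrame)) nTotal - 1L else as.integer(endFrame) - off
  if (s0 < 0L || e0 >= nTotal)
    stop(sprintf("range error: frames [%d, %d] outside video length %d",
                 s0, e0, nTotal))
  if (s0 > e0) stop("range error: startFrame must be <= endFrame")

  keep <- seq.int(s0, e0, by = sampling)   # anchored at startFrame
  if (!length(keep)) stop("empty-sequence error: no frames selected")

  first <- fetch(keep[1L] + 1L)
  arr <- array(0, dim = c(dim(first), length(keep)))
  arr[, , 1L] <- first
  for (j in seq_along(keep)[-1L]) arr[, , j] <- fetch(keep[j] + 1L)

  new("FrameSequence",
      frames = clamp01(arr),
      frameIndices = as.integer(keep),
      timestamps = keep / fps * videospeed,
      fpsSource = fps,
      pps = fps / (sampling * videospeed),
      videospeed = videospeed)
}

#' Fetch a single frame for inspection
#'
#' Returns frame \code{k} as a grey-scale matrix, handy for choosing
#' \code{startFrame}/\code{endFrame} by eye (the showFrameK role of the
#' original toolbox).
#'
#' @inheritParams loadVideo
#' @param k 0-based frame index (or 1-based with \code{oneBased = TRUE}).
#' @return numeric matrix in \code{[0, 1]}.
#' @export
getFrame <- function(video, k, fps = NULL, oneBased = FALSE) {
  k1 <- as.integer(k) + (if (isTRUE(oneBased)) 0L else 1L)
  if (is.character(video)) {
    avi <- parseAVI(video)
    if (k1 < 1L || k1 > length(avi$frameOffsets))
      stop(sprintf("range error: frame %d outside video length %d",
                   k, length(avi$frameOffsets)))
    decodeAVIFrame(avi, k1)
  } else if (is.array(video) && length(dim(video)) == 3L) {
    if (k1 < 1L || k1 > dim(video)[3L])
      stop(sprintf("range error: frame %d outside video length %d",
                   k, dim(video)[3L]))
    video[, , k1]
  } else stop("video must be a file path or an H x W x N array")
}
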