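#' Construct a ReferenceSpec
#'
#' @param mode \code{"first"}, \code{"last"} or \code{"moving_average"}.
#' @param window centered window width in frames (odd), used for
#'   \code{"moving_average"}.
#' @return a [ReferenceSpec].
#' @export
referenceSpec <- function(mode = c("first", "last", "moving_average"),
                          window = 1L) {
  new("ReferenceSpec", mode = match.arg(mode), window = as.integer(window))
}

#' Construct a PreprocessConfig
#'
#' @param smoothSigma Gaussian scale in pixels; calibrate to the apparent
#'   animal size.  0 disables smoothing.
#' @param doMask apply the static mask at \code{maskPath}.
#' @param maskPath path to a PNG mask (nonzero = keep), or \code{NA}.
#' @param cleanWhite zero pixels brighter than \code{white} in the source
#'   frame (burnt-in timestamps and overlays).
#' @param white brightness threshold in \code{[0, 1]} for \code{cleanWhite}.
#' @param threshMask intensity threshold in \code{[0, 1]} on difference maps.
#' @param threshTrim peak-intensity threshold in \code{[0, 1]} a region must
#'   exceed for its frame to count as target-containing.
#' @param disableTrim keep all frames.
#' @param polarity \code{"auto"} (detected from the data),
#'   \code{"target_darker"} or \code{"target_lighter"}.
#' @return a [PreprocessConfig].
#' @export
preprocessConfig <- function(smoothSigma = 2, doMask = FALSE,
                             maskPath = NA_character_, cleanWhite = FALSE,
                             white = 0.95, threshMask = 0.05,
                             threshTrim = 0.1, disableTrim = FALSE,
                             polarity = "auto") {
  new("PreprocessConfig",
      smoothSigma = smoothSigma, doMask = doMask,
      maskPath = as.character(maskPath), cleanWhite = cleanWhite,
      white = white, threshMask = threshMask, threshTrim = threshTrim,
      disableTrim = disableTrim, polarity = polarity)
}

#' Compute the reference frame(s) of a sequence
#'
#' The reference is subtracted from every frame to isolate the moving target.
#' \code{"first"}/\code{"last"} return one shared map; \code{"moving_average"}
#' returns a per-frame reference equal to the mean of the window of frames
#' centered on each frame (truncated at the sequence ends), which tracks slow
#' background change such as lighting or disturbed bedding.
#'
#' @param seq a [FrameSequence].
#' @param spec a [ReferenceSpec].
#' @return a matrix (shared reference) or an \code{H x W x N} array
#'   (per-frame references).
#' @export
computeReference <- function(seq, spec = referenceSpec("first")) {
  stopifnot(is(seq, "FrameSequence"), is(spec, "ReferenceSpec"))
  fr <- seq@frames
  n <- dim(fr)[3L]
  if (n < 1L) stop("empty-sequence error: no frames")
  switch(spec@mode,
    first = fr[, , 1L],
    last = fr[, , n],
    moving_average = {
      if (spec@window > n)
        stop("moving-average window exceeds sequence length")
      half <- (spec@window - 1L) %/% 2L
      # cumulative sum along time allows O(1) window means
      cs <- array(0, dim = c(dim(fr)[1:2], n + 1L))
      for (k in seq_len(n)) cs[, , k + 1L] <- cs[, , k] + fr[, , k]
      out <- array(0, dim = dim(fr))
      for (k in seq_len(n)) {
        a <- max(1L, k - half)
        b <- min(n, k + half)
        out[, , k] <- (cs[, , b + 1L] - cs[, , a]) / (b - a + 1L)
      }
      out
    })
}

#' Subtract the reference from a frame
#'
#' @param frame grey matrix.
#' @param reference grey matrix of the same shape.
#' @return signed difference map \code{frame - reference}; the target shows
#'   up negative if darker than the background, positive if lighter.
#' @export
differenceFrame <- function(frame, reference) {
  if (!identical(dim(frame), dim(reference)))
    stop("shape error: frame and reference dimensions differ")
  frame - reference
}

#' Gaussian spatial smoothing of an intensity map
#'
#' Separable convolution with a normalized Gaussian kernel truncated at
#' 3 sigma, using symmetric (edge-duplicating) reflection at the borders to
#' avoid dark halos at frame edges.  \code{sigma = 0} is the identity.
#'
#' @param x numeric matrix.
#' @param sigma kernel scale in pixels, \code{>= 0}.
#' @return smoothed matrix of the same shape.
#' @export
smoothFrame <- function(x, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(x)
  r <- as.integer(ceiling(3 * sigma))
  k <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  convAxis <- function(m, axis) {
    n <- dim(m)[axis]
    out <- array(0, dim = dim(m))
    for (o in seq.int(-r, r)) {
      idx <- reflectIndex(seq_len(n) + o, n)
      out <- out + k[o + r + 1L] *
        (if (axis == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
    }
    out
  }
  convAxis(convAxis(x, 1L), 2L)
}

#' Normalize difference polarity so target intensity is positive
#'
#' A target darker than the background produces negative values in
#' \code{frame - reference}; a lighter target, positive ones.  For a
#' consistent color mapping the stack is flipped as needed so the target is
#' always positive, and residuals of the opposite sign are clipped to zero.
#' With \code{polarity = "auto"} the direction is taken from the sign of the
#' extreme value of the summed difference stack (an all-zero stack defaults
#' to \code{"target_darker"}).
#'
#' @param diffs signed \code{H x W x N} array (or a single matrix).
#' @param polarity \code{"auto"}, \code{"target_darker"} or
#'   \code{"target_lighter"}.
#' @return list with \code{diffs} (nonnegative array) and \code{polarity}.
#' @export
normalizePolarity <- function(diffs, polarity = "auto") {
  if (is.matrix(diffs)) diffs <- array(diffs, dim = c(dim(diffs), 1L))
  if (!length(diffs)) stop("empty difference stack")
  if (polarity == "auto") {
    total <- apply(diffs, c(1L, 2L), sum)
    polarity <- if (max(total) > -min(total)) "target_lighter" else "target_darker"
  }
  out <- if (polarity == "target_darker") pmax(-diffs, 0) else pmax(diffs, 0)
  list(diffs = out, polarity = polarity)
}

#' Mask out irrelevant regions of a difference map
#'
#' Two masking mechanisms: a pre-made static mask image (zero = discard,
#' nonzero = keep), used for fixed occluders, and dynamic overlay cleaning
#' (\code{cleanWhite}) that zeroes pixels whose *source frame* intensity
#' exceeds \code{white} — this removes hard-coded timestamps or other bright
#' overlays burnt into the video.
#'
#' @param diff nonnegative difference map.
#' @param sourceFrame the original grey frame the map came from.
#' @param config a [PreprocessConfig]; only \code{cleanWhite}/\code{white}
#'   and \code{doMask} are consulted here.
#' @param staticMask optional binary matrix (nonzero = keep); required shape
#'   equal to \code{diff}.
#' @return masked difference map.
#' @export
applyMasks <- function(diff, sourceFrame, config = preprocessConfig(),
                       staticMask = NULL) {
  if (!is.null(staticMask)) {
    if (!identical(dim(diff), dim(staticMask)))
      stop("shape error: static mask dimensions differ from frame")
    diff[staticMask == 0] <- 0
  } else if (config@doMask) {
    stop("config error: doMask is set but no static mask was provided")
  }
  if (config@cleanWhite) {
    if (!identical(dim(diff), dim(sourceFrame)))
      stop("shape error: source frame dimensions differ")
    diff[sourceFrame > config@white] <- 0
  }
  diff
}

#' Trim target-free frames from the start and end
#'
#' A frame is target-containing if the binary map \code{diff > threshMask}
#' has a connected component of area at least \code{areaFloor} whose peak
#' intensity exceeds \code{threshTrim}.  Frames are retained from the first
#' to the last target-containing frame; interior frames are kept even if
#' momentarily empty, since trimming only removes from the ends.
#'
#' @param diffs nonnegative \code{H x W x N} array.
#' @param threshMask intensity threshold forming the binary map.
#' @param threshTrim peak-intensity threshold a component must exceed.
#' @param disableTrim if TRUE all frames are retained.
#' @param areaFloor minimum component area in pixels (derived from the
#'   smoothing kernel footprint by [preprocess()]).
#' @return logical vector of retained flags (one contiguous interval).
#' @export
trimFrames <- function(diffs, threshMask, threshTrim, disableTrim = FALSE,
                       areaFloor = 1L) {
  n <- dim(diffs)[3L]
  if (is.na(n) || n < 1L) stop("empty difference stack")
  if (isTRUE(disableTrim)) return(rep(TRUE, n))
  containing <- logical(n)
  for (k in seq_len(n)) {
    d <- diffs[, , k]
    if (!any(d > threshMask)) next
    if (areaFloor <= 1L && threshTrim >= threshMask) {
      containing[k] <- any(d > threshTrim)
      next
    }
    comp <- labelComponents(d > threshMask, 8L)
    big <- which(comp$sizes >= areaFloor)
    for (lab in big) {
      if (max(d[comp$labels == lab]) > threshTrim) {
        containing[k] <- TRUE
        break
      }
    }
  }
  if (!any(containing))
    stop("no-target error: no frame contains the target; ",
         "lower threshMask/threshTrim or set disableTrim")
  span <- range(which(containing))
  out <- logical(n)
  out[span[1L]:span[2L]] <- TRUE
  out
}

#' Isolate the moving target in every frame
#'
#' Runs the five pre-processing calculations in order for each sampled frame:
#' (1) subtract the reference, (2) Gaussian spatial smoothing, (3) polarity
#' normalization so target intensity is always positive, (4) static and
#' dynamic (bright-overlay) masking, and (5) trimming of target-free frames
#' from the start and end of the video.
#'
#' @param seq a [FrameSequence].
#' @param refspec a [ReferenceSpec].
#' @param config a [PreprocessConfig].
#' @param staticMask optional binary matrix (nonzero = keep); if NULL and
#'   \code{config@doMask} is set, the mask is read from \code{config@maskPath}
#'   (PNG, any nonzero channel = keep).
#' @return a [DifferenceStack].
#' @examples
#' fx <- generateFixture(fixtureSpec(nFrames = 40, size = c(48L, 64L),
#'                                   leadEmpty = 5L, tailEmpty = 5L))
#' seq <- loadVideo(fx$frames, fps = fx$fps)
#' stack <- preprocess(seq, config = preprocessConfig(smoothSigma = 1))
#' which(retained(stack))  # frames 6..35
#' @export
preprocess <- function(seq, refspec = referenceSpec("first"),
                       config = preprocessConfig(), staticMask = NULL) {
  stopifnot(is(seq, "FrameSequence"))
  validObject(config)
  ref <- computeReference(seq, refspec)
  perFrameRef <- length(dim(ref)) == 3L
  n <- nframes(seq)

  if (is.null(staticMask) && config@doMask) {
    m <- png::readPNG(config@maskPath)
    staticMask <- (if (is.matrix(m)) m else apply(m, c(1L, 2L), max)) > 0
    storage.mode(staticMask) <- "integer"
  }

  diffs <- array(0, dim = dim(seq@frames))
  for (k in seq_len(n)) {
    r <- if (perFrameRef) ref[, , k] else ref
    d <- differenceFrame(seq@frames[, , k], r)
    diffs[, , k] <- smoothFrame(d, config@smoothSigma)
  }
  np <- normalizePolarity(diffs, config@polarity)
  diffs <- np$diffs
  for (k in seq_len(n)) {
    diffs[, , k] <- applyMasks(diffs[, , k], seq@frames[, , k], config,
                               staticMask)
  }
  areaFloor <- max(1L, as.integer(ceiling(pi * config@smoothSigma^2)))
  kept <- trimFrames(diffs, config@threshMask, config@threshTrim,
                     config@disableTrim, areaFloor)
  new("DifferenceStack", diffs = diffs, retained = kept,
      timestamps = seq@timestamps, polarity = np$polarity, pps = seq@pps)
}
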