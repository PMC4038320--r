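#' Construct a FixtureSpec
#'
#' Describes a deterministic synthetic behavioural video with exact ground
#' truth, emulating the structure of a real recording: a static grey
#' background (optionally drifting slowly in brightness), a single compact
#' target darker or lighter than the background, optional additive Gaussian
#' pixel noise, an optional bright overlay rectangle standing in for a
#' burnt-in timestamp, and empty lead/tail frames before the target enters
#' and after it leaves.
#'
#' Trajectory types (time measured in video seconds from the first
#' target-containing frame; 0-based pixel coordinates):
#' \describe{
#'   \item{stationary}{\code{x}, \code{y}.}
#'   \item{linear}{\code{x0}, \code{y0}, \code{vx}, \code{vy} (px/s).}
#'   \item{circular}{\code{cx}, \code{cy}, \code{radius},
#'     \code{omega} (rad/s), optional \code{phase}.}
#'   \item{piecewise}{\code{waypoints} (m x 2 matrix of x, y) and
#'     \code{times} (length m, nondecreasing arrival times); repeating a
#'     waypoint with a later time produces a pause.}
#' }
#'
#' @param size \code{c(H, W)} in pixels.
#' @param fps frames per second.
#' @param nFrames total frame count.
#' @param background base intensity in \code{[0, 1]}.
#' @param backgroundDrift additive intensity drift per second.
#' @param blobRadius target radius in pixels.
#' @param blobAmplitude signed intensity offset (negative = darker target).
#' @param blobProfile \code{"disk"} (anti-aliased hard disk) or
#'   \code{"gaussian"} (sd = radius / 2).
#' @param trajectory list with \code{type} and parameters, see above.
#' @param leadEmpty,tailEmpty empty frame counts at the start/end.
#' @param noiseSd additive Gaussian pixel noise sd (applied after blob
#'   compositing, clipped to \code{[0, 1]}).
#' @param overlayBox optional list \code{x}, \code{y}, \code{w}, \code{h}
#'   (0-based pixels) and \code{intensity} (default 1).
#' @param seed RNG seed.
#' @return a [FixtureSpec].
#' @export
fixtureSpec <- function(size = c(240L, 320L), fps = 30, nFrames = 300L,
                        background = 0.7, backgroundDrift = 0,
                        blobRadius = 6, blobAmplitude = -0.5,
                        blobProfile = c("disk", "gaussian"),
                        trajectory = list(type = "linear", x0 = 40, y0 = 120,
                                          vx = 20, vy = 0),
                        leadEmpty = 0L, tailEmpty = 0L, noiseSd = 0,
                        overlayBox = NULL, seed = 1L) {
  new("FixtureSpec",
      size = as.integer(size), fps = fps, nFrames = as.integer(nFrames),
      background = background, backgroundDrift = backgroundDrift,
      blobRadius = blobRadius, blobAmplitude = blobAmplitude,
      blobProfile = match.arg(blobProfile), trajectory = trajectory,
      leadEmpty = as.integer(leadEmpty), tailEmpty = as.integer(tailEmpty),
      noiseSd = noiseSd,
      overlayBox = if (is.null(overlayBox)) list() else overlayBox,
      seed = as.integer(seed))
}

# evaluate a trajectory at time t (vectorized); returns cbind(x, y)
trajectoryPosition <- function(traj, t) {
  switch(traj$type,
    stationary = cbind(rep(traj$x, length(t)), rep(traj$y, length(t))),
    linear = cbind(traj$x0 + traj$vx * t, traj$y0 + traj$vy * t),
    circular = {
      ph <- if (is.null(traj$phase)) 0 else traj$phase
      cbind(traj$cx + traj$radius * cos(traj$omega * t + ph),
            traj$cy + traj$radius * sin(traj$omega * t + ph))
    },
    piecewise = {
      wp <- traj$waypoints
      tm <- traj$times
      cbind(stats::approx(tm, wp[, 1L], xout = t, rule = 2L)$y,
            stats::approx(tm, wp[, 2L], xout = t, rule = 2L)$y)
    },
    stop("unknown trajectory type: ", traj$type))
}

#' Generate a synthetic video with known ground truth
#'
#' Renders the video described by a [FixtureSpec].  The blob is drawn with
#' anti-aliased (sub-pixel coverage) edges so sub-pixel centroid recovery is
#' meaningful; noise is applied after blob compositing and the frame is
#' clipped to \code{[0, 1]}.  Deterministic given the spec's seed.
#'
#' @param spec a [FixtureSpec].
#' @param outPath optional path; when given the frames are also written as an
#'   uncompressed AVI via [writeAVI()].
#' @return list with \code{frames} (\code{H x W x N} array), \code{truth}
#'   (data.frame \code{frame} (0-based), \code{t} (video seconds), \code{x},
#'   \code{y}, \code{present}), \code{fps}, and \code{path} (NULL unless
#'   written).
#' @export
generateFixture <- function(spec, outPath = NULL) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  h <- spec@size[1L]; w <- spec@size[2L]
  n <- spec@nFrames
  first <- spec@leadEmpty          # 0-based index of first target frame
  last <- n - spec@tailEmpty - 1L  # 0-based index of last target frame
  kAll <- seq_len(n) - 1L
  tVideo <- kAll / spec@fps
  present <- kAll >= first & kAll <= last

  pos <- matrix(NA_real_, n, 2L)
  pos[present, ] <- trajectoryPosition(spec@trajectory,
                                       (kAll[present] - first) / spec@fps)
  r <- spec@blobRadius
  inFrame <- pos[present, 1L] >= r & pos[present, 1L] <= w - 1 - r &
             pos[present, 2L] >= r & pos[present, 2L] <= h - 1 - r
  if (!all(inFrame))
    stop("spec error: blob leaves the frame at target frame(s) ",
         paste(utils::head(which(!inFrame), 3L), collapse = ", "))

  xg <- matrix(rep(0:(w - 1L), each = h), h, w)   # x coordinate per pixel
  yg <- matrix(rep(0:(h - 1L), times = w), h, w)  # y coordinate per pixel

  frames <- withLocalSeed(spec@seed, {
    out <- array(0, dim = c(h, w, n))
    for (k in seq_len(n)) {
      f <- matrix(spec@background + spec@backgroundDrift * tVideo[k], h, w)
      if (present[k]) {
        dist <- sqrt((xg - pos[k, 1L])^2 + (yg - pos[k, 2L])^2)
        cov <- if (spec@blobProfile == "disk")
          pmin(1, pmax(0, r + 0.5 - dist))        # anti-aliased edge
        else exp(-dist^2 / (2 * (r / 2)^2))
        f <- f + spec@blobAmplitude * cov
      }
      if (length(spec@overlayBox)) {
        ob <- spec@overlayBox
        inten <- if (is.null(ob$intensity)) 1 else ob$intensity
        rows <- (ob$y + 1L):min(h, ob$y + ob$h)
        cols <- (ob$x + 1L):min(w, ob$x + ob$w)
        f[rows, cols] <- inten
      }
      if (spec@noiseSd > 0)
        f <- f + matrix(stats::rnorm(h * w, sd = spec@noiseSd), h, w)
      out[, , k] <- clamp01(f)
    }
    out
  })

  path <- NULL
  if (!is.null(outPath)) {
    writeAVI(frames, outPath, fps = spec@fps)
    path <- outPath
  }
  list(frames = frames,
       truth = data.frame(frame = kAll, t = tVideo,
                          x = pos[, 1L], y = pos[, 2L], present = present),
       fps = spec@fps,
       path = path)
}
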