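#' Locate the target in a difference map
#'
#' Binarizes the map at \code{threshTrim}, labels connected components
#' (8-connectivity) and returns the centroid of the largest one, provided its
#' area reaches \code{areaMin}; otherwise the target is absent.  Equal-area
#' ties are broken by higher total intensity, then by scan order.
#' Coordinates use 0-based pixel centers, origin at the top-left, x rightward
#' and y downward.
#'
#' @param diff nonnegative difference map.
#' @param threshTrim intensity threshold in \code{[0, 1]}.
#' @param areaMin minimum component area in pixels squared.
#' @param weighted if TRUE, intensity-weighted centroid instead of the binary
#'   center of mass.
#' @return named numeric \code{c(x, y)}, or NULL when no sufficiently large
#'   component exists (a valid outcome, not an error).
#' @export
detectTarget <- function(diff, threshTrim, areaMin = 1, weighted = FALSE) {
  if (min(diff) < 0) stop("difference map must be nonnegative")
  b <- diff > threshTrim
  if (!any(b)) return(NULL)
  comp <- labelComponents(b, 8L)
  big <- max(comp$sizes)
  if (big < areaMin) return(NULL)
  cand <- which(comp$sizes == big)
  if (length(cand) > 1L) {
    ints <- vapply(cand, function(l) sum(diff[comp$labels == l]), 0)
    cand <- cand[ints == max(ints)]
  }
  lab <- cand[1L]  # labels follow scan order
  idx <- which(comp$labels == lab)
  rows <- (idx - 1L) %% nrow(diff) + 1L
  cols <- (idx - 1L) %/% nrow(diff) + 1L
  w <- if (weighted) diff[idx] else rep(1, length(idx))
  c(x = sum((cols - 1) * w) / sum(w), y = sum((rows - 1) * w) / sum(w))
}

#' Extract the target's path from a difference stack
#'
#' Detects the target at \code{pathSampling} positions-per-second (path
#' extraction typically runs at a higher rate than the STL image itself).
#' Leading and trailing frames without a sufficiently large detection are
#' dropped — \code{areaMin} re-determines the start and end frames for the
#' path analysis — while interior missed detections are linearly interpolated
#' between their neighbours.  With \code{px2m} set, coordinates and path
#' length are reported in meters.
#'
#' @param stack a [DifferenceStack].
#' @param pathSampling target positions-per-second; NULL uses every frame of
#'   the stack.  Must not exceed the stack's own rate.
#' @param threshTrim intensity threshold for target detection.
#' @param areaMin minimum component area in pixels squared.
#' @param px2m optional meters-per-pixel conversion factor.
#' @param weighted use intensity-weighted centroids (see [detectTarget()]).
#' @return a [PathTrack].
#' @examples
#' fx <- generateFixture(fixtureSpec(
#'   nFrames = 60, size = c(48L, 64L),
#'   trajectory = list(type = "linear", x0 = 12, y0 = 24, vx = 15, vy = 0)))
#' stack <- preprocess(loadVideo(fx$frames, fps = fx$fps),
#'                     config = preprocessConfig(smoothSigma = 1))
#' track <- extractPath(stack, threshTrim = 0.1, areaMin = 5)
#' pathLength(track)  # ~ 15 px/s * (59/30) s
#' @export
extractPath <- function(stack, pathSampling = NULL, threshTrim = 0.1,
                        areaMin = 1, px2m = NULL, weighted = FALSE) {
  stopifnot(is(stack, "DifferenceStack"))
  n <- nframes(stack)
  step <- if (is.null(pathSampling)) 1L else {
    if (pathSampling > stack@pps + 1e-9)
      stop("pathSampling exceeds the stack's sampling rate")
    max(1L, as.integer(round(stack@pps / pathSampling)))
  }
  idx <- seq.int(1L, n, by = step)
  pos <- lapply(idx, function(k)
    detectTarget(stack@diffs[, , k], threshTrim, areaMin, weighted))
  present <- !vapply(pos, is.null, TRUE)
  if (!any(present))
    stop("no-target error: target was never detected; ",
         "check threshTrim and areaMin")
  span <- range(which(present))
  keep <- span[1L]:span[2L]
  tt <- stack@timestamps[idx[keep]]
  xs <- vapply(pos[keep], function(p) if (is.null(p)) NA_real_ else p[["x"]], 0)
  ys <- vapply(pos[keep], function(p) if (is.null(p)) NA_real_ else p[["y"]], 0)
  if (anyNA(xs)) {   # interior misses: linear interpolation in time
    ok <- !is.na(xs)
    xs[!ok] <- stats::approx(tt[ok], xs[ok], xout = tt[!ok])$y
    ys[!ok] <- stats::approx(tt[ok], ys[ok], xout = tt[!ok])$y
  }
  units <- "pixels"
  scale <- 1
  if (!is.null(px2m) && !is.na(px2m)) {
    units <- "meters"
    scale <- px2m
    xs <- xs * px2m
    ys <- ys * px2m
  }
  len <- if (length(xs) > 1L) sum(sqrt(diff(xs)^2 + diff(ys)^2)) else 0
  new("PathTrack",
      samples = data.frame(t = tt, x = xs, y = ys),
      units = units,
      px2m = if (identical(units, "meters")) px2m else NA_real_,
      pathLength = len,
      duration = tt[length(tt)] - tt[1L],
      pps = stack@pps / step)
}

# stamp a filled disk (optionally only its 1 px ring) onto an RGB array
drawMarker <- function(img, cx, cy, radius, fill = NULL, border = NULL) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  r0 <- max(1L, floor(cy + 1 - radius)); r1 <- min(h, ceiling(cy + 1 + radius))
  c0 <- max(1L, floor(cx + 1 - radius)); c1 <- min(w, ceiling(cx + 1 + radius))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  dist <- sqrt(outer((rr - 1 - cy)^2, (cc - 1 - cx)^2, `+`))
  if (!is.null(fill)) {
    inside <- dist <= radius
    for (ch in 1:3) {
      block <- img[rr, cc, ch]
      block[inside] <- fill[ch]
      img[rr, cc, ch] <- block
    }
  }
  if (!is.null(border)) {
    ring <- dist <= radius & dist > radius - 1.2
    for (ch in 1:3) {
      block <- img[rr, cc, ch]
      block[ring] <- border[ch]
      img[rr, cc, ch] <- block
    }
  }
  img
}

# stamp a 1 px-wide segment onto an RGB array by dense parametric sampling
drawSegment <- function(img, x0, y0, x1, y1, color) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  ts <- seq(0, 1, length.out = max(2L, ceiling(len * 2) + 1L))
  rows <- round(y0 + ts * (y1 - y0)) + 1L
  cols <- round(x0 + ts * (x1 - x0)) + 1L
  ok <- rows >= 1L & rows <= dim(img)[1L] & cols >= 1L & cols <= dim(img)[2L]
  for (ch in 1:3)
    img[cbind(rows[ok], cols[ok], ch)] <- color[ch]
  img
}

#' Render the path image
#'
#' Draws a time-colored marker at every track sample, connected in order by
#' segments in the border color, over the chosen background (the STL image or
#' the bare reference frame).  Marker hues follow the same time colormap as
#' the STL image so the two figures can be read together.
#'
#' @param track a [PathTrack].
#' @param background an [STLImage], RGB array or grey reference matrix.
#' @param colormap a [TimeColormap] with one color per sample; NULL builds a
#'   one-cycle map of the right length.
#' @param markerColor length-3 RGB border/segment color (usually black or
#'   white, depending on the background).
#' @param markerRadius marker radius in pixels.
#' @param outDir optional output directory; when given the image is written
#'   as \code{<stem>_path.png}.
#' @param stem file name stem used with \code{outDir}.
#' @return the RGB image array, invisibly when written to disk.
#' @export
renderPath <- function(track, background, colormap = NULL,
                       markerColor = c(0, 0, 0), markerRadius = 3,
                       outDir = NULL, stem = "track") {
  stopifnot(is(track, "PathTrack"))
  s <- track@samples
  if (!nrow(s)) stop("empty error: track has no samples")
  img <- clamp01(asRGB(if (is(background, "STLImage")) background@pixels
                       else background))
  xs <- s$x; ys <- s$y
  if (track@units == "meters" && !is.na(track@px2m)) {
    xs <- xs / track@px2m
    ys <- ys / track@px2m
  }
  if (is.null(colormap)) colormap <- buildTimeColormap(nrow(s), 1)
  if (colormap@n != nrow(s))
    stop("colormap length must match the number of samples")
  for (k in seq_len(nrow(s))[-1L])
    img <- drawSegment(img, xs[k - 1L], ys[k - 1L], xs[k], ys[k], markerColor)
  for (k in seq_len(nrow(s)))
    img <- drawMarker(img, xs[k], ys[k], markerRadius,
                      fill = colormap@colors[k, ], border = markerColor)
  if (!is.null(outDir)) {
    exportImage(img, outDir, stem, suffix = "path")
    return(invisible(img))
  }
  img
}

#' Write a track to CSV
#'
#' Columns \code{t_s,x,y,units}.
#'
#' @param track a [PathTrack].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTrackCSV <- function(track, path) {
  s <- track@samples
  df <- data.frame(t_s = s$t, x = s$x, y = s$y, units = track@units)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
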