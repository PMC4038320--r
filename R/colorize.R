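#' Build the time-to-color mapping for retained frames
#'
#' Retained frame \code{k} (0-based) of \code{n} receives the fully
#' saturated, full-value color at hue \code{(k / (n - 1)) * cycles mod 1}
#' (hue 0 when \code{n = 1}).  One cycle sweeps the hue wheel once from red
#' through the spectrum back toward red; two cycles traverse it twice, which
#' gives finer temporal resolution on long videos at the cost of ambiguity
#' between the two passes.
#'
#' @param n number of retained frames, \code{>= 1}.
#' @param cycles positive number of color-wheel cycles (typically 1 or 2).
#' @return a [TimeColormap].
#' @export
buildTimeColormap <- function(n, cycles = 1) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("empty error: need at least one frame")
  if (cycles <= 0) stop("cycles must be positive")
  h <- if (n == 1L) 0 else (((seq_len(n) - 1) / (n - 1)) * cycles) %% 1
  new("TimeColormap", n = n, cycles = cycles,
      colors = hsv2rgbMatrix(h, 1, 1))
}

#' Paint a difference map in a frame-specific color
#'
#' Pixels whose difference intensity surpasses \code{threshMask} (further
#' removing noise) are painted in the frame's color with an alpha weight
#' proportional to the intensity, normalized to the frame's maximum; all
#' other pixels are fully transparent.
#'
#' @param diff nonnegative difference map.
#' @param color length-3 RGB in \code{[0, 1]}.
#' @param threshMask intensity threshold in \code{[0, 1]}.
#' @return \code{H x W x 4} RGBA array (straight, non-premultiplied alpha).
#' @export
colorizeFrame <- function(diff, color, threshMask) {
  if (min(diff) < 0) stop("difference map must be nonnegative")
  stopifnot(length(color) == 3L)
  mx <- max(diff)
  a <- if (mx > 0) diff / mx else diff
  a[diff <= threshMask] <- 0
  out <- array(0, dim = c(dim(diff), 4L))
  out[, , 1L] <- color[1L]
  out[, , 2L] <- color[2L]
  out[, , 3L] <- color[3L]
  out[, , 4L] <- a
  out
}

#' Average colorized frames into the raw STL layer
#'
#' Per-pixel mean over the colorized frames, with transparent pixels
#' contributing zero color: the returned RGB channels are the mean of the
#' alpha-weighted colors (premultiplied), and the alpha channel is the mean
#' alpha.  A location visited in one of \code{n} frames therefore keeps its
#' own hue at \code{1/n} intensity until saturation amplification and
#' compositing restore visibility.
#'
#' @param frameList list of \code{H x W x 4} RGBA arrays of equal shape.
#' @return \code{H x W x 4} array: premultiplied mean color plus mean alpha.
#' @export
averageColorized <- function(frameList) {
  if (!length(frameList)) stop("empty error: no colorized frames")
  d <- dim(frameList[[1L]])
  out <- array(0, dim = d)
  for (f in frameList) {
    if (!identical(dim(f), d)) stop("shape error: colorized frames differ")
    a <- f[, , 4L]
    out[, , 1L] <- out[, , 1L] + f[, , 1L] * a
    out[, , 2L] <- out[, , 2L] + f[, , 2L] * a
    out[, , 3L] <- out[, , 3L] + f[, , 3L] * a
    out[, , 4L] <- out[, , 4L] + a
  }
  out / length(frameList)
}

#' Amplify the saturation of an image
#'
#' Converts to hue/saturation/value, multiplies saturation by \code{factor}
#' (clipped at 1) and converts back; hue and value are untouched.  Used to
#' restore color visibility after averaging (\code{oversatCol}) and to boost
#' the reference before compositing (\code{oversatRef}); a pure grey image is
#' a fixed point.
#'
#' @param img \code{H x W x 3} or \code{H x W x 4} array (alpha passed
#'   through untouched).
#' @param factor saturation multiplier, \code{>= 0}.
#' @return array of the same shape.
#' @export
amplifySaturation <- function(img, factor) {
  if (factor < 0) stop("factor must be >= 0")
  d <- dim(img)
  rgb <- matrix(img[, , 1:3], ncol = 3L)
  hsvm <- grDevices::rgb2hsv(t(rgb), maxColorValue = 1)
  s <- pmin(1, hsvm[2L, ] * factor)
  out <- hsv2rgbMatrix(hsvm[1L, ], s, hsvm[3L, ])
  res <- img
  res[, , 1L] <- out[, 1L]
  res[, , 2L] <- out[, 2L]
  res[, , 3L] <- out[, 3L]
  res
}

#' Fractional overlap between two thresholded target regions
#'
#' Computes \code{|A intersect B| / min(|A|, |B|)} where A and B are the
#' supra-threshold pixel sets of the two difference maps (0 if either is
#' empty).  Adjacent retained frames with overlap above \code{threshAdjac}
#' mark pauses in the movement and get a white tick in the overlap legend
#' bar.
#'
#' @param diffA,diffB nonnegative difference maps of equal shape.
#' @param threshMask intensity threshold in \code{[0, 1]}.
#' @return fraction in \code{[0, 1]}.
#' @export
computeOverlap <- function(diffA, diffB, threshMask) {
  if (!identical(dim(diffA), dim(diffB)))
    stop("shape error: maps differ in shape")
  a <- diffA > threshMask
  b <- diffB > threshMask
  na <- sum(a); nb <- sum(b)
  if (na == 0L || nb == 0L) return(0)
  sum(a & b) / min(na, nb)
}

#' Per-frame overlap flags for the legend strip
#'
#' Frame \code{k} is flagged if its thresholded target region overlaps either
#' temporal neighbour by more than \code{threshAdjac} (a stationary target
#' flags every frame).
#'
#' @param diffs nonnegative \code{H x W x N} array (retained frames only).
#' @param threshMask intensity threshold forming the regions.
#' @param threshAdjac overlap fraction above which a pair counts as
#'   overlapping.
#' @return logical vector of length N.
#' @export
overlapFlags <- function(diffs, threshMask, threshAdjac = 0.5) {
  n <- dim(diffs)[3L]
  if (n < 2L) return(rep(FALSE, n))
  pair <- vapply(seq_len(n - 1L), function(k)
    computeOverlap(diffs[, , k], diffs[, , k + 1L], threshMask), 0)
  over <- pair > threshAdjac
  c(over, FALSE) | c(FALSE, over)
}

#' Compose the final STL image
#'
#' Alpha-blends the averaged color layer over the saturation-boosted grey
#' reference: each pixel becomes \code{premultipliedColor + (1 - alpha) *
#' reference}, so locations never visited by the target equal the boosted
#' reference exactly.  Three legend bars are stacked at the bottom left
#' (2 px margins/gaps): a white real-time bar spanning \code{timeBarSec}
#' seconds, the black/white overlap strip, and the time-colormap strip; the
#' strips allot \code{pxPerFrame} pixels per retained frame so all three bars
#' are mutually comparable.
#'
#' @param avg \code{H x W x 4} output of [averageColorized()], optionally
#'   saturation-amplified.
#' @param reference grey matrix or RGB array of the same height/width.
#' @param oversatRef saturation multiplier for the reference.
#' @param colormap a [TimeColormap], or NULL to omit legend bars.
#' @param overlaps logical per retained frame (see [overlapFlags()]); NULL
#'   draws an all-black strip.
#' @param timeBarSec real-time length of the first legend bar in seconds.
#' @param barSize legend bar height in pixels.
#' @param ppsRetained positions-per-second of the retained frames, used to
#'   convert \code{timeBarSec} to strip pixels.
#' @return an [STLImage].
#' @export
composeSTL <- function(avg, reference, oversatRef = 1, colormap = NULL,
                       overlaps = NULL, timeBarSec = 10, barSize = 6L,
                       ppsRetained = 1) {
  ref3 <- clamp01(asRGB(reference))
  if (oversatRef != 1) ref3 <- amplifySaturation(ref3, oversatRef)
  d <- dim(ref3)
  if (!identical(dim(avg)[1:2], d[1:2]))
    stop("shape error: averaged layer and reference differ")
  alpha <- pmin(1, avg[, , 4L])
  out <- array(0, dim = d)
  for (ch in 1:3)
    out[, , ch] <- clamp01(avg[, , ch] + (1 - alpha) * ref3[, , ch])

  barSize <- as.integer(barSize)
  n <- if (is.null(colormap)) 0L else colormap@n
  pxf <- 0L
  timeLen <- 0L
  flags <- if (is.null(overlaps)) rep(FALSE, max(n, 0L)) else overlaps
  if (n > 0L) {
    H <- d[1L]; W <- d[2L]
    margin <- 2L; gap <- 2L
    pxf <- max(1L, (W %/% 2L) %/% n)
    stripLen <- min(n * pxf, W - 2L * margin)
    timeLen <- max(1L, min(as.integer(round(timeBarSec * ppsRetained * pxf)),
                           W - 2L * margin))
    x0 <- margin + 1L
    yBot <- H - margin                      # colormap strip rows
    yMid <- yBot - barSize - gap            # overlap strip rows
    yTop <- yMid - barSize - gap            # time bar rows
    rows <- function(yLast) max(1L, yLast - barSize + 1L):yLast
    if (yTop - barSize + 1L >= 1L) {
      out[rows(yTop), x0:(x0 + timeLen - 1L), ] <- 1       # time bar, white
      for (j in seq_len(n)) {
        xa <- x0 + (j - 1L) * pxf
        xb <- min(xa + pxf - 1L, x0 + stripLen - 1L)
        if (xa > xb) break
        out[rows(yMid), xa:xb, ] <- as.numeric(isTRUE(flags[j]))
        for (ch in 1:3)
          out[rows(yBot), xa:xb, ch] <- colormap@colors[j, ch]
      }
    }
  }
  new("STLImage", pixels = out, barSize = barSize,
      pxPerFrame = as.integer(pxf), timeBarPx = as.integer(timeLen),
      overlapFlags = as.logical(flags),
      colors = if (n > 0L) colormap@colors else matrix(0, 0L, 3L))
}

#' Export an image as a lossless PNG
#'
#' @param img an [STLImage], an RGB(A) array, or a grey matrix.
#' @param outDir output directory; created (recursively) if missing.
#' @param stem file name stem; the file is \code{<stem>_<suffix>.png}.
#' @param suffix name suffix, default \code{"stl"}.
#' @return the written file path.
#' @export
exportImage <- function(img, outDir, stem, suffix = "stl") {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create output directory ", outDir)
  px <- if (is(img, "STLImage")) img@pixels else img
  if (is.matrix(px)) px <- asRGB(px)
  path <- file.path(outDir, paste0(stem, "_", suffix, ".png"))
  png::writePNG(clamp01(px), path)
  path
}
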