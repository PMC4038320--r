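# Minimal RIFF/AVI container support for uncompressed 24-bit DIB video.
# No video decoder ships with this R stack, so the reference input format
# (uncompressed AVI) is read and written directly.  Only biCompression == 0
# with 24 bits per pixel is supported; anything else raises a decode error.

u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
fourcc <- function(s) charToRaw(s)

readU32 <- function(raw, at) {
  # unsigned 32-bit little-endian; R integers are signed so go via doubles
  b <- as.integer(raw[at:(at + 3L)])
  b[1L] + b[2L] * 256 + b[3L] * 65536 + b[4L] * 16777216
}

readU16 <- function(raw, at) {
  b <- as.integer(raw[at:(at + 1L)])
  b[1L] + b[2L] * 256
}

#' Write frames to an uncompressed AVI file
#'
#' Encodes grey-scale frames as uncompressed 24-bit DIB video (each channel
#' carrying the same intensity byte) in a standard RIFF/AVI container with an
#' idx1 index.  The round trip through [loadVideo()] is exact up to the
#' 8-bit quantization of 1/255 per pixel.
#'
#' @param frames numeric \code{H x W x N} array (or a single matrix) with
#'   values in \code{[0, 1]}.
#' @param path output file path.
#' @param fps frames per second to record in the header.
#' @return the file path, invisibly.
#' @seealso [loadVideo()], [generateFixture()]
#' @export
writeAVI <- function(frames, path, fps = 30) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L, fps > 0)
  d <- dim(frames)
  h <- d[1L]; w <- d[2L]; n <- d[3L]
  rowBytes <- w * 3L
  pad <- (4L - rowBytes %% 4L) %% 4L
  frameBytes <- (rowBytes + pad) * h

  scale <- 1000L
  rate <- as.integer(round(fps * 1000))

  avih <- c(
    u32raw(round(1e6 / fps)),        # dwMicroSecPerFrame
    u32raw(frameBytes * fps),        # dwMaxBytesPerSec
    u32raw(0L),                      # dwPaddingGranularity
    u32raw(16L),                     # dwFlags: AVIF_HASINDEX
    u32raw(n),                       # dwTotalFrames
    u32raw(0L),                      # dwInitialFrames
    u32raw(1L),                      # dwStreams
    u32raw(frameBytes),              # dwSuggestedBufferSize
    u32raw(w), u32raw(h),
    u32raw(0L), u32raw(0L), u32raw(0L), u32raw(0L)
  )
  strh <- c(
    fourcc("vids"), fourcc("DIB "),
    u32raw(0L),                      # dwFlags
    u16raw(0L), u16raw(0L),          # priority, language
    u32raw(0L),                      # dwInitialFrames
    u32raw(scale), u32raw(rate),     # fps = rate / scale
    u32raw(0L), u32raw(n),           # dwStart, dwLength
    u32raw(frameBytes),              # dwSuggestedBufferSize
    u32raw(0L),                      # dwQuality (default)
    u32raw(0L),                      # dwSampleSize
    u16raw(0L), u16raw(0L), u16raw(w), u16raw(h)  # rcFrame
  )
  strf <- c(
    u32raw(40L),                     # biSize
    u32raw(w), u32raw(h),
    u16raw(1L), u16raw(24L),         # planes, bit count
    u32raw(0L),                      # biCompression: BI_RGB
    u32raw(frameBytes),
    u32raw(0L), u32raw(0L), u32raw(0L), u32raw(0L)
  )
  chunk <- function(id, payload) c(fourcc(id), u32raw(length(payload)), payload)
  listChunk <- function(type, payload)
    c(fourcc("LIST"), u32raw(length(payload) + 4L), fourcc(type), payload)

  strl <- listChunk("strl", c(chunk("strh", strh), chunk("strf", strf)))
  hdrl <- listChunk("hdrl", c(chunk("avih", avih), strl))

  # movi payload: one 00db chunk per frame; bottom-up rows, BGR, padded to 4
  frameRaw <- function(k) {
    bytes <- as.integer(round(clamp01(frames[, , k]) * 255))
    m <- matrix(bytes, nrow = h)[h:1L, , drop = FALSE]   # bottom-up rows
    rowMajor <- as.vector(t(m))                          # row-by-row, l-to-r
    bgr <- rep(rowMajor, each = 3L)                      # B = G = R
    if (pad > 0L) {
      padded <- matrix(0L, nrow = rowBytes + pad, ncol = h)
      padded[seq_len(rowBytes), ] <- matrix(bgr, nrow = rowBytes)
      as.raw(padded)
    } else as.raw(bgr)
  }

  moviSize <- 4L + n * (8L + frameBytes)
  idxSize <- n * 16L
  riffSize <- 4L +                       # 'AVI '
    8L + length(hdrl) - 8L + 8L +        # hdrl LIST (already has own header)
    0L
  # compute RIFF size directly: everything after the first 8 bytes
  riffSize <- 4L + length(hdrl) + (8L + moviSize) + (8L + idxSize)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(fourcc("RIFF"), u32raw(riffSize), fourcc("AVI ")), con)
  writeBin(hdrl, con)
  writeBin(c(fourcc("LIST"), u32raw(moviSize), fourcc("movi")), con)
  offsets <- numeric(n)
  pos <- 4L  # offset within movi payload, from just after 'movi'
  for (k in seq_len(n)) {
    offsets[k] <- pos
    writeBin(c(fourcc("00db"), u32raw(frameBytes), frameRaw(k)), con)
    pos <- pos + 8L + frameBytes
  }
  idx <- raw(0L)
  for (k in seq_len(n)) {
    idx <- c(idx, fourcc("00db"), u32raw(16L),  # AVIIF_KEYFRAME
             u32raw(offsets[k]), u32raw(frameBytes))
  }
  writeBin(c(fourcc("idx1"), u32raw(idxSize), idx), con)
  invisible(path)
}

# Parse an AVI file into header metadata plus per-frame chunk offsets.
# Returns list(fps, width, height, bitCount, frameOffsets, frameSizes, raw).
parseAVI <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop("cannot read video file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rw <- readBin(con, "raw", n = sz)
  if (length(rw) < 12L || rawToChar(rw[1:4]) != "RIFF" ||
      rawToChar(rw[9:12]) != "AVI ")
    stop("decode error: not a RIFF/AVI file: ", path)

  out <- new.env()
  out$frameOffsets <- numeric(0L)
  out$frameSizes <- numeric(0L)

  scanChunks <- function(from, to) {
    pos <- from
    while (pos + 8L <= to + 1L) {
      id <- rawToChar(rw[pos:(pos + 3L)])
      size <- readU32(rw, pos + 4L)
      body <- pos + 8L
      if (id == "LIST") {
        scanChunks(body + 4L, body + size - 1L)
      } else if (id == "avih") {
        out$usecPerFrame <- readU32(rw, body)
        out$width <- readU32(rw, body + 32L)
        out$height <- readU32(rw, body + 36L)
      } else if (id == "strh") {
        if (rawToChar(rw[body:(body + 3L)]) == "vids") {
          out$scale <- readU32(rw, body + 20L)
          out$rate <- readU32(rw, body + 24L)
        }
      } else if (id == "strf" && is.null(out$bitCount)) {
        out$strfWidth <- readU32(rw, body + 4L)
        out$strfHeight <- readU32(rw, body + 8L)
        out$bitCount <- readU16(rw, body + 14L)
        out$compression <- readU32(rw, body + 16L)
      } else if (grepl("^[0-9]{2}d[bc]$", id)) {
        out$frameOffsets <- c(out$frameOffsets, body)
        out$frameSizes <- c(out$frameSizes, size)
      }
      pos <- body + size + size %% 2  # chunks are word-aligned
    }
  }
  scanChunks(13L, length(rw))

  if (is.null(out$width)) stop("decode error: missing avih header in ", path)
  if (is.null(out$bitCount) || out$compression != 0 || out$bitCount != 24L)
    stop("decode error: only uncompressed 24-bit DIB AVI is supported")
  fps <- if (!is.null(out$rate) && !is.null(out$scale) && out$scale > 0)
    out$rate / out$scale else 1e6 / out$usecPerFrame
  list(fps = fps, width = out$width, height = out$height,
       frameOffsets = out$frameOffsets, frameSizes = out$frameSizes, raw = rw)
}

# decode frame k (1-based) of a parsed AVI to a grey matrix in [0,1]
decodeAVIFrame <- function(avi, k) {
  w <- avi$width; h <- avi$height
  rowBytes <- w * 3L
  stride <- rowBytes + (4L - rowBytes %% 4L) %% 4L
  at <- avi$frameOffsets[k]
  bytes <- as.integer(avi$raw[at:(at + stride * h - 1L)])
  m <- matrix(bytes, nrow = stride)[seq_len(rowBytes), , drop = FALSE]
  b <- m[seq(1L, rowBytes, by = 3L), , drop = FALSE]   # W x H, rows bottom-up
  g <- m[seq(2L, rowBytes, by = 3L), , drop = FALSE]
  r <- m[seq(3L, rowBytes, by = 3L), , drop = FALSE]
  grey <- (0.299 * r + 0.587 * g + 0.114 * b) / 255     # luma weighting
  t(grey)[h:1L, , drop = FALSE]
}
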