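test_that("time colormap follows the hue formula and wraps across cycles", {
  # n = 5, one cycle: hues 0, 0.25, 0.5, 0.75, 1 -> 0 (wraps)
  cm <- buildTimeColormap(5L, 1)
  hues <- unname(apply(frameColors(cm), 1L, function(rgb)
    grDevices::rgb2hsv(rgb[1L], rgb[2L], rgb[3L], maxColorValue = 1)[1L, ]))
  expect_equal(hues, c(0, 0.25, 0.5, 0.75, 0), tolerance = 1e-12)
  # n = 10, two cycles: brute-force hue formula
  cm2 <- buildTimeColormap(10L, 2)
  hues2 <- unname(apply(frameColors(cm2), 1L, function(rgb)
    grDevices::rgb2hsv(rgb[1L], rgb[2L], rgb[3L], maxColorValue = 1)[1L, ]))
  expect_equal(hues2, ((0:9) / 9 * 2) %% 1, tolerance = 1e-12)
  # degenerate single frame: red
  expect_equal(frameColors(buildTimeColormap(1L))[1L, ],
               c(r = 1, g = 0, b = 0), ignore_attr = TRUE)
  expect_error(buildTimeColormap(0L), "empty error")
})

test_that("hue monotonicity holds within the first color cycle", {
  for (n in c(5L, 12L, 33L)) for (cyc in c(1, 2)) {
    cm <- buildTimeColormap(n, cyc)
    hues <- apply(frameColors(cm), 1L, function(rgb)
      grDevices::rgb2hsv(rgb[1L], rgb[2L], rgb[3L], maxColorValue = 1)[1L, ])
    raw <- ((seq_len(n) - 1) / (n - 1)) * cyc
    first <- which(raw < 1)  # indices within the first cycle, before wrap
    expect_true(all(diff(hues[first]) > 0))
  }
})

test_that("colorizeFrame paints supra-threshold pixels with proportional alpha", {
  d <- matrix(0, 10L, 10L)
  d[2:4, 2:4] <- 0.6            # supra-threshold blob
  d[7:8, 7:8] <- 0.04           # sub-threshold blob
  out <- colorizeFrame(d, c(1, 0, 0), threshMask = 0.05)
  expect_equal(dim(out), c(10L, 10L, 4L))
  expect_true(all(out[2:4, 2:4, 4L] == 1))          # normalized to frame max
  expect_true(all(out[7:8, 7:8, 4L] == 0))          # sub-threshold transparent
  expect_true(all(out[2:4, 2:4, 1L] == 1) && all(out[, , 2:3] == 0))
  # proportional weighting
  d[5L, 5L] <- 0.3
  out2 <- colorizeFrame(d, c(0, 1, 0), threshMask = 0.05)
  expect_equal(out2[5L, 5L, 4L], 0.5)
  # all-zero map is fully transparent
  expect_true(all(colorizeFrame(matrix(0, 4L, 4L), c(1, 0, 0), 0.1)[, , 4L] == 0))
})

test_that("averaging keeps disjoint blobs in their own color at reduced intensity", {
  a <- colorizeFrame(diskDiff(20L, 20L, 5, 5, 2, 0.5), c(1, 0, 0), 0.05)
  b <- colorizeFrame(diskDiff(20L, 20L, 14, 14, 2, 0.5), c(0, 0, 1), 0.05)
  avg <- averageColorized(list(a, b))
  # hand-computed mean at the blob centers: own color at half intensity
  expect_equal(avg[6L, 6L, 1L], 0.5)
  expect_equal(avg[6L, 6L, 3L], 0)
  expect_equal(avg[15L, 15L, 3L], 0.5)
  expect_equal(avg[15L, 15L, 1L], 0)
  # identity (modulo premultiplication) and idempotency of the mean
  aPre <- a
  for (ch in 1:3) aPre[, , ch] <- a[, , ch] * a[, , 4L]
  expect_equal(averageColorized(list(a)), aPre)
  rep3 <- averageColorized(list(b, b, b))
  expect_equal(rep3, averageColorized(list(b)))
  # averaging bound: never exceeds the per-channel max over inputs
  expect_true(all(avg[, , 1:3] <= pmax(a[, , 1:3], b[, , 1:3]) + 1e-12))
  expect_error(averageColorized(list()), "empty error")
})

test_that("saturation amplification scales saturation and preserves hue and value", {
  img <- array(0, dim = c(1L, 1L, 3L))
  img[1L, 1L, ] <- c(0.8, 0.48, 0.48)   # hue 0, s = 0.4, v = 0.8
  out <- amplifySaturation(img, 2)
  hsvo <- grDevices::rgb2hsv(out[1, 1, 1], out[1, 1, 2], out[1, 1, 3],
                             maxColorValue = 1)
  expect_equal(unname(hsvo[2L, 1L]), 0.8, tolerance = 1e-12)  # saturation doubled
  expect_equal(unname(hsvo[1L, 1L]), 0, tolerance = 1e-12)    # hue unchanged
  expect_equal(unname(hsvo[3L, 1L]), 0.8, tolerance = 1e-12)  # value unchanged
  # factor 1 is the identity; grey is a fixed point for any factor
  expect_equal(amplifySaturation(img, 1), img, tolerance = 1e-12)
  grey <- array(0.6, dim = c(2L, 2L, 3L))
  expect_equal(amplifySaturation(grey, 5), grey, tolerance = 1e-12)
  # clipping at full saturation
  out2 <- amplifySaturation(img, 10)
  hsv2 <- grDevices::rgb2hsv(out2[1, 1, 1], out2[1, 1, 2], out2[1, 1, 3],
                             maxColorValue = 1)
  expect_equal(unname(hsv2[2L, 1L]), 1)
})

test_that("overlap fraction is intersection over the smaller region", {
  a <- matrix(0, 10L, 10L); a[1:4, 1:4] <- 0.5    # 16 px
  b <- matrix(0, 10L, 10L); b[3:4, 1:4] <- 0.5    # 8 px, fully inside a
  expect_equal(computeOverlap(a, a, 0.1), 1)
  expect_equal(computeOverlap(a, b, 0.1), 1)      # b subset of a
  d <- matrix(0, 10L, 10L); d[8:10, 8:10] <- 0.5
  expect_equal(computeOverlap(a, d, 0.1), 0)      # disjoint
  # half of the smaller set shared: b has 8 px, c shares 4 of them
  cc <- matrix(0, 10L, 10L); cc[4L, 1:4] <- 0.5; cc[6L, 1:4] <- 0.5
  expect_equal(computeOverlap(b, cc, 0.1), 0.5)
  expect_equal(computeOverlap(a, matrix(0, 10L, 10L), 0.1), 0)
  expect_error(computeOverlap(a, matrix(0, 3L, 3L), 0.1), "shape error")
})

test_that("compositing conservation: untouched pixels equal the boosted reference", {
  set.seed(3)
  ref <- matrix(runif(30 * 40, 0.2, 0.8), 30L, 40L)
  d <- diskDiff(30L, 40L, 20, 15, 3, 0.5)
  avg <- averageColorized(list(colorizeFrame(d, c(0, 1, 0), 0.05)))
  stl <- composeSTL(avg, ref, oversatRef = 1.5)  # no legend bars (colormap NULL)
  px <- pixels(stl)
  untouched <- avg[, , 4L] == 0
  boosted <- amplifySaturation(asRGBForTest(ref), 1.5)
  for (ch in 1:3)
    expect_equal(px[, , ch][untouched], boosted[, , ch][untouched])
  # the blob region is green-shifted
  expect_gt(px[16L, 21L, 2L], px[16L, 21L, 1L])
})

test_that("legend bars are drawn with the documented geometry", {
  ref <- matrix(0.5, 60L, 120L)
  n <- 10L
  cm <- buildTimeColormap(n, 1)
  avg <- array(0, dim = c(60L, 120L, 4L))
  flags <- rep(c(TRUE, FALSE), 5L)
  stl <- composeSTL(avg, ref, colormap = cm, overlaps = flags,
                    timeBarSec = 2, barSize = 4L, ppsRetained = 1)
  px <- pixels(stl)
  pxf <- stl@pxPerFrame
  expect_equal(pxf, (120L %/% 2L) %/% n)
  expect_equal(stl@timeBarPx, 2L * pxf)  # timeBar seconds x pps x px/frame
  # colormap strip occupies the bottom bar: first cell is red
  expect_equal(px[60L - 2L, 3L, ], c(1, 0, 0))
  # overlap strip alternates white/black per frame cell
  yMid <- 60L - 2L - 4L - 2L
  expect_equal(px[yMid, 3L, ], c(1, 1, 1))
  expect_equal(px[yMid, 3L + pxf, ], c(0, 0, 0))
  # time bar is white and of the computed length
  yTop <- yMid - 4L - 2L
  expect_equal(px[yTop, 3L, ], c(1, 1, 1))
  expect_equal(px[yTop, 3L + stl@timeBarPx, ], c(0.5, 0.5, 0.5))
})

test_that("export writes a lossless PNG with the naming contract", {
  out <- file.path(tempfile(), "nested", "dir")   # created on demand
  set.seed(5)
  img <- array(runif(20 * 20 * 3), dim = c(20L, 20L, 3L))
  p <- exportImage(img, out, "trial1")
  expect_equal(basename(p), "trial1_stl.png")
  expect_true(file.exists(p))
  back <- png::readPNG(p)
  expect_lte(max(abs(back - img)), 1 / 255 / 2 + 1e-9)  # 8-bit quantization
  # STLImage input and alternate suffix
  ref <- matrix(0.5, 8L, 8L)
  stl <- composeSTL(array(0, dim = c(8L, 8L, 4L)), ref)
  p2 <- exportImage(stl, out, "trial1", suffix = "path")
  expect_equal(basename(p2), "trial1_path.png")
})
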