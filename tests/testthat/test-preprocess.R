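test_that("reference modes: first, last, and brute-force moving average", {
  # linear-ramp sequence: frame k has constant intensity k/10
  arr <- array(rep((1:8) / 10, each = 25L), dim = c(5L, 5L, 8L))
  seq <- loadVideo(arr, fps = 10)
  expect_equal(computeReference(seq, referenceSpec("first")), arr[, , 1L])
  expect_equal(computeReference(seq, referenceSpec("last")), arr[, , 8L])
  ref <- computeReference(seq, referenceSpec("moving_average", 3L))
  expect_equal(dim(ref), dim(arr))
  for (k in 1:8) {
    win <- max(1L, k - 1L):min(8L, k + 1L)  # brute-force window mean
    expected <- apply(arr[, , win, drop = FALSE], c(1L, 2L), mean)
    expect_equal(ref[, , k], expected)
  }
  # constant video: any mode returns the constant frame
  carr <- array(0.4, dim = c(4L, 4L, 6L))
  cseq <- loadVideo(carr, fps = 10)
  for (spec in list(referenceSpec("first"), referenceSpec("last"),
                    referenceSpec("moving_average", 5L)))
    expect_true(all(abs(computeReference(cseq, spec) - 0.4) < 1e-12))
})

test_that("difference maps are signed frame minus reference", {
  ref <- matrix(0.8, 10L, 10L)
  frame <- ref
  frame[4:6, 4:6] <- 0.3  # dark blob on light background
  d <- differenceFrame(frame, ref)
  expect_true(all(d[4:6, 4:6] == -0.5))   # negative at the blob
  expect_true(all(d[-(4:6), ] == 0))
  expect_equal(differenceFrame(ref, ref), matrix(0, 10L, 10L))
  expect_error(differenceFrame(frame, matrix(0, 3L, 3L)), "shape error")
})

test_that("Gaussian smoothing matches brute-force convolution with reflected boundary", {
  set.seed(7)
  x <- matrix(runif(25), 5L, 5L)
  expect_lt(max(abs(smoothFrame(x, 1) - bruteGaussianSmooth(x, 1))), 1e-10)
  expect_lt(max(abs(smoothFrame(x, 0.6) - bruteGaussianSmooth(x, 0.6))), 1e-10)
  # constant map unchanged (kernel sums to 1) and sigma 0 is the identity
  cm <- matrix(0.37, 9L, 7L)
  expect_equal(smoothFrame(cm, 2), cm)
  expect_identical(smoothFrame(x, 0), x)
  # impulse response equals the normalized discretized kernel
  imp <- matrix(0, 15L, 15L)
  imp[8L, 8L] <- 1
  sm <- smoothFrame(imp, 1)
  r <- 3L
  k1 <- exp(-(-r:r)^2 / 2)
  k2 <- outer(k1, k1) / sum(outer(k1, k1))
  expect_lt(max(abs(sm[5:11, 5:11] - k2)), 1e-12)
  expect_equal(sum(sm), 1)
})

test_that("polarity normalization flips dark targets and reports polarity", {
  d <- array(0, dim = c(6L, 6L, 3L))
  d[2:3, 2:3, ] <- -0.4   # dark target: negative differences
  np <- normalizePolarity(d)
  expect_equal(np$polarity, "target_darker")
  expect_true(all(np$diffs >= 0))
  expect_true(all(np$diffs[2:3, 2:3, ] == 0.4))
  # light target
  np2 <- normalizePolarity(-d)
  expect_equal(np2$polarity, "target_lighter")
  expect_true(all(np2$diffs[2:3, 2:3, ] == 0.4))
  # degenerate all-zero stack defaults to target_darker
  np3 <- normalizePolarity(array(0, dim = c(4L, 4L, 2L)))
  expect_equal(np3$polarity, "target_darker")
  expect_true(all(np3$diffs == 0))
  # explicit override clips the opposite sign
  np4 <- normalizePolarity(d, polarity = "target_lighter")
  expect_true(all(np4$diffs == 0))
})

test_that("masking removes static regions and bright overlays, and is idempotent", {
  d <- matrix(0.3, 8L, 12L)
  src <- matrix(0.5, 8L, 12L)
  src[1:2, 1:4] <- 1      # white timestamp box in the source frame
  cfg <- preprocessConfig(cleanWhite = TRUE, white = 0.95)
  out <- applyMasks(d, src, cfg)
  expect_true(all(out[1:2, 1:4] == 0))
  expect_true(all(out[3:8, ] == 0.3))
  # all-ones static mask with cleanWhite off is the identity
  id <- applyMasks(d, src, preprocessConfig(), staticMask = matrix(1L, 8L, 12L))
  expect_identical(id, d)
  # static mask zeroing the left half
  m <- matrix(1L, 8L, 12L)
  m[, 1:6] <- 0L
  out2 <- applyMasks(d, src, preprocessConfig(), staticMask = m)
  expect_true(all(out2[, 1:6] == 0) && all(out2[, 7:12] == 0.3))
  # idempotence
  expect_identical(applyMasks(out2, src, preprocessConfig(), staticMask = m),
                   out2)
  expect_error(applyMasks(d, src, preprocessConfig(), matrix(1L, 2L, 2L)),
               "shape error")
  expect_error(
    applyMasks(d, src, preprocessConfig(doMask = TRUE, maskPath = "m.png")),
    "config error")
})

test_that("trimming retains exactly the contiguous target-containing span", {
  n <- 30L
  diffs <- array(0, dim = c(20L, 20L, n))
  for (k in 10:20) diffs[, , k] <- diskDiff(20L, 20L, 10, 10, 3, 0.5)
  kept <- trimFrames(diffs, threshMask = 0.05, threshTrim = 0.1)
  expect_equal(which(kept), 10:20)
  # interior gaps are kept: trimming removes only from the ends
  diffs[, , 15L] <- 0
  kept2 <- trimFrames(diffs, threshMask = 0.05, threshTrim = 0.1)
  expect_equal(which(kept2), 10:20)
  # disableTrim retains everything
  expect_true(all(trimFrames(diffs, 0.05, 0.1, disableTrim = TRUE)))
  # blob present everywhere: all retained
  all_ <- array(rep(diskDiff(20L, 20L, 10, 10, 3, 0.5), n),
                dim = c(20L, 20L, n))
  expect_true(all(trimFrames(all_, 0.05, 0.1)))
  # no target at all
  expect_error(trimFrames(array(0, dim = c(20L, 20L, 3L)), 0.05, 0.1),
               "no-target error")
})

test_that("raising threshTrim never increases the number of retained frames", {
  set.seed(11)
  n <- 12L
  diffs <- array(runif(15 * 15 * n, 0, 0.05), dim = c(15L, 15L, n))
  for (k in 4:9)
    diffs[, , k] <- diffs[, , k] + diskDiff(15L, 15L, 7, 7, 3, 0.3 + 0.05 * k)
  counts <- vapply(seq(0.05, 0.9, by = 0.05), function(tt) {
    kept <- tryCatch(trimFrames(diffs, 0.1, tt), error = function(e) logical(n))
    sum(kept)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("preprocess composite isolates the target and trims empty lead/tail", {
  fx <- smallLinearFixture(nFrames = 45L, lead = 9L, tail = 12L)
  seq <- loadVideo(fx$frames, fps = fx$fps)
  stack <- preprocess(seq, config = preprocessConfig(smoothSigma = 1))
  expect_s4_class(stack, "DifferenceStack")
  expect_equal(polarity(stack), "target_darker")
  expect_true(min(frames(stack)) >= 0)  # nonnegativity invariant
  expect_equal(which(retained(stack)), 10:33)
  expect_equal(timestamps(stack), timestamps(seq))
  # retained flags mark one contiguous interval (validity enforces too)
  r <- which(retained(stack))
  expect_equal(r, r[1L]:r[length(r)])
  # empty video with disableTrim: all retained, all-zero diffs
  empty <- array(0.6, dim = c(20L, 20L, 5L))
  st2 <- preprocess(loadVideo(empty, fps = 10),
                    config = preprocessConfig(disableTrim = TRUE))
  expect_true(all(retained(st2)))
  expect_equal(max(frames(st2)), 0)
})

test_that("a light target is handled symmetrically to a dark one", {
  fx <- generateFixture(fixtureSpec(
    size = c(60L, 80L), nFrames = 30L, blobAmplitude = 0.25, background = 0.3,
    blobRadius = 4,
    trajectory = list(type = "linear", x0 = 15, y0 = 30, vx = 30, vy = 0),
    leadEmpty = 4L, tailEmpty = 4L))
  stack <- preprocess(loadVideo(fx$frames, fps = fx$fps),
                      config = preprocessConfig(smoothSigma = 1))
  expect_equal(polarity(stack), "target_lighter")
  expect_equal(which(retained(stack)), 5:26)
})

test_that("cleanWhite suppresses a flickering timestamp overlay in the pipeline", {
  # a burnt-in timestamp whose content changes frame to frame would otherwise
  # register as spurious motion in the difference maps
  fx <- generateFixture(fixtureSpec(
    size = c(60L, 80L), nFrames = 24L, blobRadius = 4,
    trajectory = list(type = "linear", x0 = 15, y0 = 40, vx = 30, vy = 0),
    leadEmpty = 4L, tailEmpty = 4L))
  arr <- fx$frames
  for (k in seq_len(dim(arr)[3L]))
    arr[3:8, 3:22, k] <- ifelse(k %% 2L == 1L, 1, 0.97)
  seq <- loadVideo(arr, fps = fx$fps)
  cfg <- preprocessConfig(smoothSigma = 1, cleanWhite = TRUE, white = 0.95)
  stack <- preprocess(seq, config = cfg)
  expect_true(all(frames(stack)[3:8, 3:22, ] == 0))
  expect_equal(which(retained(stack)), 5:20)
  # without cleanWhite the flicker leaks into the difference maps
  stackRaw <- preprocess(seq, config = preprocessConfig(smoothSigma = 1))
  expect_gt(max(frames(stackRaw)[3:8, 3:22, ]), 0)
})
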