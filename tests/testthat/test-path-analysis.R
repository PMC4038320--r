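test_that("component labelling and largest-centroid detection match a brute-force oracle", {
  set.seed(21)
  for (rep in 1:5) {
    b <- matrix(runif(20 * 20) < 0.3, 20L, 20L)
    comp <- labelComponents(b, 8L)
    oracle <- bruteLabel(b, 8L)
    # identical partitions (labels assigned in the same scan order)
    expect_identical(comp$labels, matrix(as.integer(oracle), 20L, 20L))
    expect_equal(comp$sizes, as.integer(table(oracle[oracle > 0L])),
                 ignore_attr = TRUE)
  }
  # 4- vs 8-connectivity: a diagonal pair is one component only under 8
  diag2 <- matrix(FALSE, 5L, 5L)
  diag2[2L, 2L] <- diag2[3L, 3L] <- TRUE
  expect_equal(length(labelComponents(diag2, 8L)$sizes), 1L)
  expect_equal(length(labelComponents(diag2, 4L)$sizes), 2L)
})

test_that("detectTarget returns the centroid of the largest component", {
  # symmetric disk: centroid within 0.5 px of the true center
  d <- diskDiff(100L, 120L, 50, 60, 5, 0.5)
  pos <- detectTarget(d, threshTrim = 0.1)
  expect_lt(abs(pos[["x"]] - 50), 0.5)
  expect_lt(abs(pos[["y"]] - 60), 0.5)
  # two components of area 120 and 40: the larger one wins (oracle-checked)
  d2 <- matrix(0, 30L, 30L)
  d2[2:11, 2:13] <- 0.4    # 10 x 12 = 120 px
  d2[20:24, 20:27] <- 0.4  # 5 x 8 = 40 px
  pos2 <- detectTarget(d2, 0.1)
  oracle <- bruteLabel(d2 > 0.1, 8L)
  sizes <- table(oracle[oracle > 0L])
  big <- as.integer(names(which.max(sizes)))
  idx <- which(oracle == big)
  expect_equal(pos2[["x"]], mean((idx - 1L) %/% 30L))
  expect_equal(pos2[["y"]], mean((idx - 1L) %% 30L))
  # area_min gate: largest component below the floor means absent
  expect_null(detectTarget(d2, 0.1, areaMin = 200))
  expect_null(detectTarget(matrix(0, 10L, 10L), 0.1))
  # intensity-weighted centroid shifts toward the brighter side
  d3 <- matrix(0, 11L, 11L)
  d3[6L, 4:8] <- c(0.2, 0.2, 0.2, 0.8, 0.8)
  expect_gt(detectTarget(d3, 0.1, weighted = TRUE)[["x"]],
            detectTarget(d3, 0.1)[["x"]])
})

test_that("extractPath recovers straight-line paths and trims undetected ends", {
  fx <- smallLinearFixture(nFrames = 42L, lead = 6L, tail = 6L, vx = 30)
  stack <- preprocess(loadVideo(fx$frames, fps = fx$fps),
                      config = preprocessConfig(smoothSigma = 1))
  track <- extractPath(stack, threshTrim = 0.1, areaMin = 10)
  s <- trackSamples(track)
  # detections start when the target appears and end when it leaves
  expect_equal(nrow(s), 30L)
  expect_equal(s$t[1L], 6 / 30)
  # straight line at constant speed: path length = (n-1) * d
  truth <- fx$truth[fx$truth$present, ]
  expect_equal(pathLength(track), 29L * (30 / 30), tolerance = 0.01)
  expect_equal(trackDuration(track), 29 / 30)
  # per-sample agreement with ground truth
  rmse <- sqrt(mean((s$x - truth$x)^2 + (s$y - truth$y)^2))
  expect_lt(rmse, 1)
  expect_error(extractPath(stack, threshTrim = 0.99), "no-target error")
})

test_that("interior missed detections are linearly interpolated", {
  fx <- smallLinearFixture(nFrames = 30L, lead = 4L, tail = 4L, vx = 30)
  stack <- preprocess(loadVideo(fx$frames, fps = fx$fps),
                      config = preprocessConfig(smoothSigma = 1))
  # knock the target out of three interior frames
  stack@diffs[, , 12:14] <- 0
  track <- extractPath(stack, threshTrim = 0.1, areaMin = 10)
  s <- trackSamples(track)
  expect_equal(nrow(s), 22L)  # span unchanged: 5..26
  truth <- fx$truth[fx$truth$present, ]
  expect_lt(max(abs(s$x - truth$x)), 0.5)  # linear motion interpolates exactly
})

test_that("px2m scaling is exactly equivariant", {
  fx <- smallLinearFixture(nFrames = 30L, lead = 4L, tail = 4L)
  stack <- preprocess(loadVideo(fx$frames, fps = fx$fps),
                      config = preprocessConfig(smoothSigma = 1))
  px <- extractPath(stack, threshTrim = 0.1, areaMin = 10)
  m1 <- extractPath(stack, threshTrim = 0.1, areaMin = 10, px2m = 0.01)
  m2 <- extractPath(stack, threshTrim = 0.1, areaMin = 10, px2m = 0.02)
  expect_equal(m1@units, "meters")
  expect_equal(pathLength(m1), 0.01 * pathLength(px))
  expect_equal(pathLength(m2), 2 * pathLength(m1))
  expect_equal(trackSamples(m2)$x, 2 * trackSamples(m1)$x)
  expect_equal(trackDuration(m1), trackDuration(px))
})

test_that("circular trajectories: polyline length approaches the circumference", {
  fx <- generateFixture(fixtureSpec(
    size = c(200L, 200L), fps = 30, nFrames = 219L, blobRadius = 5,
    trajectory = list(type = "circular", cx = 100, cy = 100, radius = 60,
                      omega = 2 * pi / 7),  # one revolution in 7 s
    leadEmpty = 8L, seed = 2L))
  stack <- preprocess(loadVideo(fx$frames, fps = fx$fps))
  track <- extractPath(stack, threshTrim = 0.1, areaMin = 10)
  # 211 samples over 7 s: dense polyline within 2% of 2*pi*r
  expect_equal(pathLength(track), 2 * pi * 60, tolerance = 0.02)
})

test_that("path length respects triangle inequality and polyline refinement", {
  fx <- generateFixture(fixtureSpec(
    size = c(120L, 160L), fps = 30, nFrames = 100L, blobRadius = 4,
    trajectory = list(type = "piecewise",
                      waypoints = rbind(c(20, 20), c(120, 30), c(120, 90),
                                        c(40, 90), c(40, 90)),
                      times = c(0, 1, 2, 2.8, 3)),  # ends with a pause
    leadEmpty = 5L, tailEmpty = 4L, seed = 3L))
  stack <- preprocess(loadVideo(fx$frames, fps = fx$fps))
  fine <- extractPath(stack, threshTrim = 0.1, areaMin = 10)
  coarse <- extractPath(stack, pathSampling = 6, threshTrim = 0.1, areaMin = 10)
  s <- trackSamples(fine)
  straight <- sqrt(diff(range(s$x[c(1L, nrow(s))]))^2 +
                   (s$y[nrow(s)] - s$y[1L])^2)
  expect_gte(pathLength(fine), straight)
  # coarser sampling never lengthens a noiseless polyline
  expect_lte(pathLength(coarse), pathLength(fine) + 1e-9)
  expect_equal(pps(coarse), 6)
})

test_that("stationary targets give zero path length over the full duration", {
  fx <- generateFixture(fixtureSpec(
    size = c(60L, 80L), fps = 10, nFrames = 110L, blobRadius = 4,
    trajectory = list(type = "stationary", x = 40, y = 30),
    leadEmpty = 5L, tailEmpty = 4L, seed = 4L))
  stack <- preprocess(loadVideo(fx$frames, fps = fx$fps))
  track <- extractPath(stack, threshTrim = 0.1, areaMin = 10)
  expect_equal(pathLength(track), 0)
  expect_equal(trackDuration(track), 10)
})

test_that("renderPath draws colormap-hued markers with the border color", {
  fx <- smallLinearFixture(nFrames = 24L, lead = 4L, tail = 4L, vx = 30)
  stack <- preprocess(loadVideo(fx$frames, fps = fx$fps),
                      config = preprocessConfig(smoothSigma = 1))
  track <- extractPath(stack, pathSampling = 6, threshTrim = 0.1, areaMin = 10)
  s <- trackSamples(track)
  cm <- buildTimeColormap(nrow(s), 1)
  img <- renderPath(track, matrix(0.5, 60L, 80L), colormap = cm,
                    markerColor = c(0, 0, 0), markerRadius = 3)
  # marker centers carry the frame-specific colormap color
  for (k in c(1L, nrow(s))) {
    px <- img[round(s$y[k]) + 1L, round(s$x[k]) + 1L, ]
    expect_equal(px, cm@colors[k, ], ignore_attr = TRUE)
  }
  # border pixels in the marker color exist near each sample
  k <- 2L
  nb <- img[round(s$y[k]) + 1L + (-4:4), round(s$x[k]) + 1L + (-4:4), 1L]
  expect_true(any(nb == 0))
  # single-sample track: one marker, no segments
  one <- track
  one@samples <- s[1L, , drop = FALSE]
  one@pathLength <- 0; one@duration <- 0
  img1 <- renderPath(one, matrix(0.5, 60L, 80L), markerRadius = 2)
  expect_equal(sum(img1[, , 1L] != 0.5) > 0, TRUE)
  # CSV export contract
  p <- tempfile(fileext = ".csv")
  writeTrackCSV(track, p)
  got <- utils::read.csv(p)
  expect_identical(names(got), c("t_s", "x", "y", "units"))
  expect_equal(got$x, s$x, tolerance = 1e-6)
})
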