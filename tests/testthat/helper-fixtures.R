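# shared fixture builders and independent brute-force oracles

# a small linear-trajectory fixture with a clean (target-free) lead so the
# first-frame reference contains no target
smallLinearFixture <- function(nFrames = 60L, lead = 6L, tail = 6L,
                               size = c(60L, 80L), vx = 30, vy = 0,
                               x0 = 15, y0 = 30, radius = 4, seed = 1L,
                               noiseSd = 0, fps = 30) {
  generateFixture(fixtureSpec(
    size = size, fps = fps, nFrames = nFrames, blobRadius = radius,
    trajectory = list(type = "linear", x0 = x0, y0 = y0, vx = vx, vy = vy),
    leadEmpty = lead, tailEmpty = tail, noiseSd = noiseSd, seed = seed))
}

# direct 2-D convolution with a normalized Gaussian kernel and symmetric
# (edge-duplicating) reflection; deliberately naive
bruteGaussianSmooth <- function(x, sigma) {
  r <- as.integer(ceiling(3 * sigma))
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2))
  k2 <- outer(k1, k1)
  k2 <- k2 / sum(k2)
  h <- nrow(x); w <- ncol(x)
  refl <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 1L - i
      if (i > n) i <- 2L * n + 1L - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + k2[di + r + 1L, dj + r + 1L] *
        x[refl(i + di, h), refl(j + dj, w)]
    out[i, j] <- acc
  }
  out
}

# naive connected-component labelling by repeated label propagation
bruteLabel <- function(binary, connectivity = 8L) {
  b <- binary != 0
  h <- nrow(b); w <- ncol(b)
  lab <- matrix(0L, h, w)
  lab[b] <- seq_len(sum(b))  # provisional unique labels in scan order
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  repeat {
    changed <- FALSE
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (!b[i, j]) next
      for (o in offs) {
        ii <- i + o[1L]; jj <- j + o[2L]
        if (ii >= 1L && ii <= h && jj >= 1L && jj <= w && b[ii, jj] &&
            lab[ii, jj] < lab[i, j]) {
          lab[i, j] <- lab[ii, jj]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # renumber in order of first appearance
  u <- unique(lab[lab > 0L])
  out <- lab
  for (k in seq_along(u)) out[lab == u[k]] <- k
  out
}

# centered weighted moving average by direct per-index summation
bruteWeightedSmooth <- function(v, w) {
  r <- (length(w) - 1L) %/% 2L
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (o in -r:r) {
      j <- i + o
      if (j >= 1L && j <= n) {
        num <- num + w[o + r + 1L] * v[j]
        den <- den + w[o + r + 1L]
      }
    }
    out[i] <- num / den
  }
  out
}

# place an anti-aliased disk of given peak amplitude on a zero map
diskDiff <- function(h, w, cx, cy, radius, amplitude = 0.5) {
  xg <- matrix(rep(0:(w - 1L), each = h), h, w)
  yg <- matrix(rep(0:(h - 1L), times = w), h, w)
  d <- sqrt((xg - cx)^2 + (yg - cy)^2)
  matrix(amplitude * pmin(pmax(radius + 0.5 - d, 0), 1), h, w)
}

# grey matrix -> H x W x 3 array (test-local, independent of package internals)
asRGBForTest <- function(m) {
  out <- array(0, dim = c(dim(m), 3L))
  out[, , 1L] <- m; out[, , 2L] <- m; out[, , 3L] <- m
  out
}
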