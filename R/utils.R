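# small internal helpers shared across stages

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# symmetric (edge-duplicating) reflection of 1-based indices onto 1..n
reflectIndex <- function(i, n) {
  i <- (i - 1L) %% (2L * n)
  ifelse(i < n, i + 1L, 2L * n - i)
}

# grey matrix -> H x W x 3, or pass an RGB(A) array through as RGB
asRGB <- function(x) {
  if (is.matrix(x)) {
    out <- array(0, dim = c(dim(x), 3L))
    out[, , 1L] <- x; out[, , 2L] <- x; out[, , 3L] <- x
    return(out)
  }
  d <- dim(x)
  if (length(d) == 3L && d[3L] >= 3L) return(x[, , 1:3, drop = FALSE])
  stop("cannot interpret input as an RGB image")
}

# vectorized continuous HSV -> RGB (grDevices::hsv quantizes via col2rgb)
hsv2rgbMatrix <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  tt <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, tt, v)))))
  g <- ifelse(i == 0, tt, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, tt,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b, deparse.level = 0L)
}

# run code with a locally seeded RNG, restoring the caller's RNG state
withLocalSeed <- function(seed, code) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
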