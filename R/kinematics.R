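#' Instantaneous velocity of a track
#'
#' Uses the distances travelled between time points, as calculated for the
#' path analysis: \code{v_k = |sample_{k+1} - sample_k| / (t_{k+1} - t_k)},
#' a nonnegative speed placed at the midpoint of each interval.
#'
#' @param track a [PathTrack] with at least 2 samples.
#' @return a [KinematicsSeries] with the velocity part filled in (the
#'   acceleration part is empty; see [accelerationSeries()]).
#' @export
velocitySeries <- function(track) {
  stopifnot(is(track, "PathTrack"))
  s <- track@samples
  if (nrow(s) < 2L)
    stop("insufficient-data error: need at least 2 samples for velocity")
  dt <- diff(s$t)
  v <- sqrt(diff(s$x)^2 + diff(s$y)^2) / dt
  new("KinematicsSeries",
      tVel = (s$t[-nrow(s)] + s$t[-1L]) / 2,
      velocity = v,
      tAcc = numeric(0L), acceleration = numeric(0L),
      weights = 1, units = track@units)
}

#' Instantaneous acceleration from a velocity series
#'
#' \code{a_k = (v_{k+1} - v_k) / dt} between velocity midpoints; values may
#' be negative (deceleration).  Acceleration timestamps sit at the midpoints
#' of the velocity midpoints.
#'
#' @param series a [KinematicsSeries] with at least 2 velocity values.
#' @return the series with the acceleration part filled in.
#' @export
accelerationSeries <- function(series) {
  stopifnot(is(series, "KinematicsSeries"))
  v <- series@velocity
  if (length(v) < 2L)
    stop("insufficient-data error: need at least 2 velocity values")
  tv <- series@tVel
  series@acceleration <- diff(v) / diff(tv)
  series@tAcc <- (tv[-length(tv)] + tv[-1L]) / 2
  series
}

#' Centered weighted moving average
#'
#' Smooths a series with odd-length nonnegative weights summing to 1.  At the
#' ends, where the window is truncated, the remaining weights are
#' renormalized, so a constant series is always left unchanged.
#'
#' @param values numeric series.
#' @param weights odd-length nonnegative weights summing to 1.
#' @return smoothed series of the same length.
#' @export
smoothSeries <- function(values, weights = c(0.25, 0.5, 0.25)) {
  if (!length(values)) stop("config error: empty series")
  if (length(weights) %% 2L == 0L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("config error: weights must be odd-length, nonnegative, summing to 1")
  r <- (length(weights) - 1L) %/% 2L
  n <- length(values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    w <- weights[j - i + r + 1L]
    out[i] <- sum(w * values[j]) / sum(w)
  }
  out
}

#' Velocity and acceleration of a track, with weighted smoothing
#'
#' Convenience wrapper for the full kinematics stage: computes the raw
#' velocity series, smooths it with the given weights, derives acceleration
#' from the smoothed velocities, and smooths the accelerations with the same
#' weights.
#'
#' @param track a [PathTrack] with at least 3 samples.
#' @param weights smoothing weights (see [smoothSeries()]); default
#'   \code{c(0.25, 0.5, 0.25)}.
#' @return a [KinematicsSeries].
#' @export
computeKinematics <- function(track, weights = c(0.25, 0.5, 0.25)) {
  series <- velocitySeries(track)
  series@velocity <- smoothSeries(series@velocity, weights)
  series <- accelerationSeries(series)
  series@acceleration <- smoothSeries(series@acceleration, weights)
  series@weights <- weights
  series
}

#' Plot velocity and acceleration against time
#'
#' Writes \code{<stem>_vel.png}: velocity on the left axis, acceleration on
#' the right axis, time on the abscissa covering the full series.
#'
#' @param series a [KinematicsSeries].
#' @param outDir output directory, created if missing.
#' @param stem file name stem.
#' @param width,height plot size in pixels.
#' @return the written file path.
#' @export
renderVelocityPlot <- function(series, outDir, stem, width = 800,
                               height = 480) {
  stopifnot(is(series, "KinematicsSeries"))
  if (!length(series@velocity)) stop("empty error: no velocity values")
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create output directory ", outDir)
  path <- file.path(outDir, paste0(stem, "_vel.png"))
  u <- if (series@units == "meters") "m" else "px"
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  xlim <- range(c(series@tVel, series@tAcc))
  pad <- function(r) {
    if (diff(r) > max(1e-6, abs(mean(r)) * 1e-6)) r
    else mean(r) + c(-1, 1) * max(0.5, abs(mean(r)) * 0.1)
  }
  graphics::par(mar = c(4.5, 4.5, 2, 4.5))
  plot(series@tVel, series@velocity, type = "l", col = "#1b61a8", lwd = 2,
       xlim = xlim, ylim = pad(range(series@velocity)), xlab = "time (s)",
       ylab = sprintf("velocity (%s/s)", u))
  if (length(series@acceleration)) {
    graphics::par(new = TRUE)
    plot(series@tAcc, series@acceleration, type = "l", col = "#c23b22",
         lwd = 2, lty = 2, xlim = xlim, ylim = pad(range(series@acceleration)),
         axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4L)
    graphics::mtext(sprintf("acceleration (%s/s²)", u), side = 4L,
                    line = 3)
    graphics::abline(h = 0, col = "grey70", lty = 3)
  }
  graphics::legend("topright", legend = c("velocity", "acceleration"),
                   col = c("#1b61a8", "#c23b22"), lty = c(1, 2), bty = "n")
  path
}

#' Write a kinematics series to CSV
#'
#' Columns \code{t_s,velocity,acceleration}; the acceleration column is blank
#' on the last velocity row (there is one fewer acceleration than velocity).
#'
#' @param series a [KinematicsSeries].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeKinematicsCSV <- function(series, path) {
  nv <- length(series@velocity)
  acc <- rep(NA_real_, nv)
  na <- length(series@acceleration)
  if (na) acc[seq_len(na)] <- series@acceleration
  df <- data.frame(t_s = series@tVel, velocity = series@velocity,
                   acceleration = acc)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
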