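#' Default run configuration
#'
#' A named list of every user-facing setting, grouped as in the original
#' toolbox and keyed by the same names: input (\code{path_raw},
#' \code{sampling}, \code{startFrame}, \code{endFrame}, \code{videospeed}),
#' reference (\code{refFrame}, \code{refSmooth}), preprocessing
#' (\code{smooth}, \code{doMask}, \code{maskName}, \code{cleanWhite},
#' \code{white}, \code{threshMask}, \code{threshTrim}, \code{disableTrim},
#' \code{polarity}), rendering (\code{cmap}, \code{oversatCol},
#' \code{oversatRef}, \code{timeBar}, \code{threshAdjac}, \code{barSize}),
#' path analysis (\code{doPath}, \code{pathSampling}, \code{pathBack},
#' \code{pathCol}, \code{areamin}, \code{px2m}), kinematics (\code{doVel},
#' \code{velSmooth}) and output (\code{path_out}).  All intensity thresholds
#' are on the normalized \code{[0, 1]} scale.
#'
#' @return named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    # input
    path_raw = NULL,       # video file path
    sampling = 30L,        # keep every i-th frame (30 fps video -> 1 pps)
    startFrame = NULL,     # 0-based, inclusive
    endFrame = NULL,
    videospeed = 1,        # real-time multiplier (0.1 = 10x-slowed source)
    # reference
    refFrame = "first",    # "first", "last" or "moving_average"
    refSmooth = 15L,       # moving-average window (frames, odd)
    # preprocessing
    smooth = 2,            # Gaussian sigma in px; calibrate to animal size
    doMask = FALSE,
    maskName = NULL,       # static mask image (PNG, nonzero = keep)
    cleanWhite = FALSE,
    white = 0.95,
    threshMask = 0.05,
    threshTrim = 0.1,
    disableTrim = FALSE,
    polarity = "auto",     # or "target_darker" / "target_lighter"
    # rendering
    cmap = 1,              # color cycles
    oversatCol = 2,
    oversatRef = 1,
    timeBar = 10,          # seconds represented by the first legend bar
    threshAdjac = 0.5,
    barSize = 6L,
    # path analysis
    doPath = TRUE,
    pathSampling = 6,      # positions-per-second for path extraction
    pathBack = "stl",      # "stl" or "ref"
    pathCol = "black",     # or "white"
    areamin = 20,          # px^2
    px2m = NULL,           # meters per pixel
    # kinematics
    doVel = TRUE,
    velSmooth = c(0.25, 0.5, 0.25),
    # output
    path_out = "."
  )
}

validateConfig <- function(cfg) {
  bad <- character()
  inUnit <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  for (key in c("threshMask", "threshTrim", "white", "threshAdjac"))
    if (!inUnit(cfg[[key]]))
      bad <- c(bad, sprintf("%s must be a number in [0, 1]", key))
  if (!is.numeric(cfg$sampling) || cfg$sampling < 1)
    bad <- c(bad, "sampling must be a positive integer")
  if (!is.numeric(cfg$videospeed) || cfg$videospeed <= 0)
    bad <- c(bad, "videospeed must be positive")
  if (!cfg$refFrame %in% c("first", "last", "moving_average"))
    bad <- c(bad, "refFrame must be 'first', 'last' or 'moving_average'")
  if (!is.numeric(cfg$smooth) || cfg$smooth < 0)
    bad <- c(bad, "smooth must be >= 0")
  if (!is.numeric(cfg$cmap) || cfg$cmap <= 0)
    bad <- c(bad, "cmap must be > 0")
  for (key in c("oversatCol", "oversatRef"))
    if (!is.numeric(cfg[[key]]) || cfg[[key]] < 0)
      bad <- c(bad, sprintf("%s must be >= 0", key))
  if (!is.numeric(cfg$barSize) || cfg$barSize < 1)
    bad <- c(bad, "barSize must be >= 1")
  if (!is.numeric(cfg$pathSampling) || cfg$pathSampling <= 0)
    bad <- c(bad, "pathSampling must be > 0")
  if (!is.numeric(cfg$areamin) || cfg$areamin < 0)
    bad <- c(bad, "areamin must be >= 0")
  w <- cfg$velSmooth
  if (!is.numeric(w) || length(w) %% 2L == 0L || any(w < 0) ||
      abs(sum(w) - 1) > 1e-8)
    bad <- c(bad, "velSmooth must be odd-length nonnegative weights summing to 1")
  if (!is.null(cfg$startFrame) && !is.null(cfg$endFrame) &&
      cfg$startFrame > cfg$endFrame)
    bad <- c(bad, "startFrame must be <= endFrame")
  if (isTRUE(cfg$doMask) && is.null(cfg$maskName))
    bad <- c(bad, "doMask is set but maskName is missing")
  if (isTRUE(cfg$doVel) && !isTRUE(cfg$doPath))
    bad <- c(bad, "doVel requires doPath (kinematics derive from the path)")
  if (length(bad))
    stop("config error:\n  - ", paste(bad, collapse = "\n  - "))
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a flat YAML key-value file whose keys match the setting names of
#' [defaultConfig()]; omitted keys take their documented defaults, unknown
#' keys raise a warning, and invalid values raise a single error listing all
#' violations.
#'
#' @param path YAML file path.
#' @return validated named list.
#' @export
loadConfig <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- defaultConfig()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    warning("unknown config keys ignored: ", paste(unknown, collapse = ", "))
  for (key in intersect(names(user), names(cfg)))
    cfg[[key]] <- if (is.list(user[[key]])) unlist(user[[key]]) else user[[key]]
  validateConfig(cfg)
}

#' Run the full pipeline on a video
#'
#' Executes the stages in order: load/sample (A), preprocess (B), colorize
#' (C), average and oversaturate (D), compose and export the STL image (E),
#' then optionally path analysis (F) and the velocity-acceleration plot (G).
#' Writes \code{<stem>_stl.png} and, when enabled, \code{<stem>_path.png} +
#' \code{<stem>_path.csv} and \code{<stem>_vel.png} + \code{<stem>_vel.csv}.
#'
#' @param config named list as returned by [loadConfig()]/[defaultConfig()].
#' @param video optional video path or frame array overriding
#'   \code{config$path_raw}.
#' @param outDir optional output directory overriding \code{config$path_out}.
#' @param stem file name stem for all outputs.
#' @param fps frames-per-second, required when \code{video} is an in-memory
#'   array.
#' @param quiet suppress progress messages.
#' @return invisible list: \code{files} (named vector of written paths),
#'   \code{fps}, \code{pps}, \code{retainedSpan} (first/last retained frame,
#'   1-based within the sampled sequence), \code{pathLength},
#'   \code{duration}, \code{track}, \code{kinematics}, \code{stl}.
#' @export
runPipeline <- function(config = defaultConfig(), video = NULL, outDir = NULL,
                        stem = "stl", fps = NULL, quiet = FALSE) {
  cfg <- validateConfig(config)
  if (is.null(video)) video <- cfg$path_raw
  if (is.null(video)) stop("config error: no input video (path_raw)")
  if (is.null(outDir)) outDir <- cfg$path_out
  say <- function(...) if (!quiet) message(sprintf(...))

  # A: load and sample
  seq <- loadVideo(video, sampling = cfg$sampling, startFrame = cfg$startFrame,
                   endFrame = cfg$endFrame, videospeed = cfg$videospeed,
                   fps = fps)
  say("stage A: %d frames; source %g fps, STL %g pps", nframes(seq),
      fpsSource(seq), pps(seq))
  refspec <- referenceSpec(cfg$refFrame, if (cfg$refFrame == "moving_average")
    cfg$refSmooth else 1L)
  pconf <- preprocessConfig(
    smoothSigma = cfg$smooth, doMask = isTRUE(cfg$doMask),
    maskPath = if (is.null(cfg$maskName)) NA_character_ else cfg$maskName,
    cleanWhite = isTRUE(cfg$cleanWhite), white = cfg$white,
    threshMask = cfg$threshMask, threshTrim = cfg$threshTrim,
    disableTrim = isTRUE(cfg$disableTrim), polarity = cfg$polarity)

  # B: preprocess
  stack <- preprocess(seq, refspec, pconf)
  kept <- which(retained(stack))
  span <- range(kept)
  say("stage B: polarity %s; retained frames %d..%d of %d (%.1f s)",
      polarity(stack), span[1L], span[2L], nframes(stack),
      diff(range(timestamps(stack)[kept])))

  # C + D: colorize, average, oversaturate
  cmap <- buildTimeColormap(length(kept), cfg$cmap)
  colorized <- lapply(seq_along(kept), function(j)
    colorizeFrame(stack@diffs[, , kept[j]], cmap@colors[j, ], cfg$threshMask))
  avg <- averageColorized(colorized)
  avg <- amplifySaturation(avg, cfg$oversatCol)

  # E: compose and export
  ref <- computeReference(seq, refspec)
  if (length(dim(ref)) == 3L) ref <- ref[, , kept[1L]]
  flags <- overlapFlags(stack@diffs[, , kept, drop = FALSE], cfg$threshMask,
                        cfg$threshAdjac)
  stl <- composeSTL(avg, ref, oversatRef = cfg$oversatRef, colormap = cmap,
                    overlaps = flags, timeBarSec = cfg$timeBar,
                    barSize = cfg$barSize, ppsRetained = pps(stack))
  files <- c(stl = exportImage(stl, outDir, stem))
  say("stage E: wrote %s", files[["stl"]])

  track <- NULL
  kin <- NULL
  if (isTRUE(cfg$doPath)) {
    # F: path analysis at its own (usually finer) sampling rate
    samplingPath <- max(1L, as.integer(round(
      fpsSource(seq) / (cfg$pathSampling * cfg$videospeed))))
    seqPath <- loadVideo(video, sampling = samplingPath,
                         startFrame = cfg$startFrame, endFrame = cfg$endFrame,
                         videospeed = cfg$videospeed, fps = fps)
    stackPath <- preprocess(seqPath, refspec, pconf)
    track <- extractPath(stackPath, threshTrim = cfg$threshTrim,
                         areaMin = cfg$areamin, px2m = cfg$px2m)
    say("stage F: %d positions at %g pps; path length %.3f %s over %.2f s",
        nrow(trackSamples(track)), pps(track), pathLength(track),
        track@units, trackDuration(track))
    bg <- if (identical(cfg$pathBack, "ref")) ref else stl
    markerColor <- if (identical(cfg$pathCol, "white")) c(1, 1, 1) else c(0, 0, 0)
    renderPath(track, bg,
               colormap = buildTimeColormap(nrow(trackSamples(track)),
                                            cfg$cmap),
               markerColor = markerColor, outDir = outDir, stem = stem)
    files["path_image"] <- file.path(outDir, paste0(stem, "_path.png"))
    files["path_csv"] <- file.path(outDir, paste0(stem, "_path.csv"))
    writeTrackCSV(track, files[["path_csv"]])

    if (isTRUE(cfg$doVel)) {
      # G: kinematics
      kin <- computeKinematics(track, cfg$velSmooth)
      files["vel_plot"] <- renderVelocityPlot(kin, outDir, stem)
      files["vel_csv"] <- file.path(outDir, paste0(stem, "_vel.csv"))
      writeKinematicsCSV(kin, files[["vel_csv"]])
      say("stage G: %d velocity values, smoothing weights %s",
          length(velocity(kin)),
          paste(signif(cfg$velSmooth, 3L), collapse = "/"))
    }
  }

  invisible(list(files = files, fps = fpsSource(seq), pps = pps(seq),
                 retainedSpan = span,
                 pathLength = if (is.null(track)) NA_real_ else pathLength(track),
                 duration = if (is.null(track)) NA_real_ else trackDuration(track),
                 track = track, kinematics = kin, stl = stl))
}
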