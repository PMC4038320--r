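Package: stlapse
Title: Spectral Time-Lapse Images and Markerless Single-Target Tracking
        from Behavioural Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Summarizes an animal's movement in a pre-recorded video as a
        single spectral time-lapse (STL) image, in which the target's
        position at each sampled time is painted in a time-specific color
        over a reference frame of the video. Includes markerless
        single-target tracking via background subtraction and
        largest-connected-component centroid detection, yielding the x/y
        path, total path length, duration, and smoothed instantaneous
        velocity and acceleration. Reads uncompressed AVI video directly,
        ships a deterministic synthetic-video generator with exact ground
        truth for validation, and exposes every stage (reference
        computation, Gaussian smoothing, polarity normalization, masking,
        trimming, time-to-color mapping, compositing, path extraction,
        kinematics) as a documented function.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, grDevices, graphics, stats, utils, png, yaml
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
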