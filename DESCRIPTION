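Package: drfparams
Title: Automated Radiographic Parameters for Distal Radius Fractures
Version: 0.1.0
Authors@R:
    person("drfparams", "maintainers", email = "drfparams@example.org",
           role = c("aut", "cre"))
Description: Geometric post-processing pipeline that turns biplane (AP and
    lateral) wrist bone segmentation masks into the four radiographic
    parameters used to grade distal radius fractures: radial angle (RA),
    radial length (RL), ulnar variance (UV) and palmar tilt (PT). Includes
    label-mask PNG input/output with histogram-equalization preprocessing,
    contour extraction (flood-fill hole closing, Gaussian denoising, Sobel
    edges, largest-contour selection, triangle-based simplification),
    robust central-axis fitting with a smoothed-Manhattan loss minimized by
    gradient descent, rotating-line detection of the five anatomical
    landmarks (styloid tip, ulnar border of radius, ulnar height, dorsal
    joint rim, volar joint border), reference implementations of common
    segmentation losses, and a ground-truthed synthetic wrist phantom
    generator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
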