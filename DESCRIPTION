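Package: flymodes
Title: Segmentation and Symbolic Analysis of Fruit Fly Locomotor Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: High-content phenotyping of fruit fly locomotion from
    centroid and body-axis tracking data. Resolves the head/tail ambiguity of
    axis-valued orientation angles, smooths trajectories with repeated running
    medians and local linear (LOWESS-type) regression to estimate speed and
    angular velocities, derives data-intrinsic segmentation thresholds from
    intersections of Gaussian mixture components fitted by EM, classifies every
    frame into one of six coordination modes (fixed or rotating front on a
    straight or curved path, lingering, rotation in place), digitizes the
    angular interval between direction of progression and body orientation,
    and summarizes sessions as symbolic mode sequences, phase-wise mode
    proportions, rotational-episode statistics, drug-stage labels and
    mode-transition matrices. Includes a synthetic-session generator with
    ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
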