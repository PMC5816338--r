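Package: vvorkit
Title: Automated Analysis of Visually Enhanced Vestibulo-Ocular Reflex Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automated, device-independent analysis of visually
    enhanced vestibulo-ocular reflex (VVOR) recordings exported as CSV time
    series of head and eye angular velocity. Removes nystagmus fast phases
    from the eye-velocity channel with a one-dimensional median filter
    ("desaccading"), computes directional VVOR gain by two independent
    methods (area under the curve of head and eye velocity, and the slope of
    the eye-versus-head scatter plot fitted through the origin), assesses the
    head-oscillation frequency by fast Fourier transform, detects fast-phase
    saccades in the desaccading residual and reports saccades per second and
    per stimulation cycle, and quantifies agreement between the two gain
    methods with the intra-class correlation coefficient and Bland-Altman
    limits of agreement. A synthetic-trace generator with pathology presets
    (healthy, bilateral and unilateral vestibulopathy, CANVAS) provides
    ground-truth recordings for validation without any device data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
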