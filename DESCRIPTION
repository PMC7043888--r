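Package: vipramp
Title: Simulation and Analysis of VIP Interneuron Dynamics in a Visual Change-Detection Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to simulate a go/no-go visual change-detection task
    (periodic natural-image flashes with occasional identity changes and
    stimulus omissions), to generate synthetic calcium event traces for
    excitatory and VIP inhibitory cell populations under familiar and novel
    stimulus conditions, and to compute the associated behavioral and neural
    response metrics: hit/false-alarm rates and d-prime, engagement masks,
    windowed flash and omission responses, resampling-based responsiveness
    classification, lifetime sparseness, population tuning curves,
    time-to-peak, pre-stimulus/stimulus/omission ramp indices, and
    image-set group comparisons (ANOVA plus pairwise Welch tests with
    Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
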