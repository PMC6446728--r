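Package: ivmtracks
Title: Motility and Anomalous-Diffusion Analysis of Intravital Cell Tracks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing single-cell trajectories exported from
    intravital microscopy spot tracking: per-track motility statistics
    (mean speed, local displacement, distinct sites visited),
    time-averaged mean-squared displacement (TA-MSD) estimation with
    anomalous-diffusion exponent fitting and motion-regime
    classification, and paired/unpaired cohort comparisons of the kind
    used to study leukemia cell migration in the bone marrow before and
    after CXCR4 antagonism. Includes an exactly-seeded synthetic
    trajectory generator (Brownian, fractional Brownian, persistent
    random walk, ballistic) emulating a paired pre/post-drug timelapse
    design, so every analysis stage can be validated against known
    motion models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
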