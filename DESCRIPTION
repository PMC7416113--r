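Package: chromarg
Title: Spectral-Temporal Typing and Morphometrics of Retinal Ganglion Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for analysing
    larval zebrafish retinal ganglion cell (RGC) function and morphology.
    Generates tetrachromatic binary-noise stimuli and linear-nonlinear
    calcium responses with known ground truth; estimates per-channel
    spectral-temporal kernels by calcium-event-triggered reverse
    correlation; classifies kernels by polarity, ternary cone-wiring state,
    chromatic opponency and spectral centroid; bins any per-ROI statistic
    into circularly smoothed Eye-IPL maps; clusters response profiles with
    a Gaussian-mixture BIC sweep over four covariance structures; and
    quantifies dendritic morphology via convex-hull and stratification
    summaries, two-stage hierarchical clustering with cophenetic
    validation, and soma-centred dendritic-tilt statistics including a
    two-sample Kuiper test for circular data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
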