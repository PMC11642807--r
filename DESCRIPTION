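Package: tauspreadr
Title: Connectome-Based Linear Diffusion Modelling of Tau Pathology Spread
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the spread of tau pathology over a directed brain
    connectome as linear diffusion from seed regions via the matrix
    exponential of the out-degree graph Laplacian. Provides tools to load
    and validate region atlases, connectivity matrices and per-mouse
    regional pathology cohorts; to fit the diffusion rate constant against
    observed regional pathology; to combine anterograde, retrograde and
    Euclidean-distance spread predictions (plus neuronal-activity tdT
    density and its treatment interactions) in multivariate regressions
    with standardized beta weights, simple slopes and partial residuals;
    to compare bootstrap distributions of model fits with a two-tailed
    non-parametric test and FDR correction; and to assess seed specificity
    against spatially matched random seed sets. A synthetic-data module
    generates atlas, connectome, cohort and behavioral fixtures with known
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
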