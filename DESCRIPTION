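Package: spikeglm
Title: Point-Process GLM Analysis of Functional Connectivity in Ensemble
    Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits discrete-time point-process generalized linear models to
    simultaneously recorded spike trains and infers directed, signed
    (excitatory/inhibitory) functional connectivity among neurons.  The
    conditional intensity of each cell is modelled log-linearly in lagged
    spike counts of the whole ensemble over millisecond-scale history
    windows; coefficients are estimated by ridge-penalized maximum
    likelihood with cross-validated regularization and BIC window
    selection, model adequacy is checked by the time-rescaling theorem and
    Kolmogorov-Smirnov test, and connections are declared from Wald
    confidence intervals.  Includes a ground-truth spike-train simulator
    for the same model family, connectivity summary statistics (mean E+I
    connectivity ratio, E:I balance, cell-group interaction fractions),
    condition comparisons, and split-half / trial-shuffle Monte-Carlo
    controls.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
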