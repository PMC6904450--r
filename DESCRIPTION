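Package: sadscaling
Title: Species Abundance Distribution Scaling and Richness Extrapolation
    for Microbial Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood fitting of heavy-tailed species abundance
    distributions (pure, truncated, double and shifted power laws, lognormal,
    Weibull) to OTU read-count tables, with AIC-based model selection.
    Implements the zeta-function theory linking the abundance-distribution
    exponent to the scaling of species richness with sequencing effort,
    rarefaction (species accumulation) curves with gamma-exponent fitting,
    and in-silico community generation at arbitrary sequencing depth from
    parameter-versus-effort trajectories, quantifying how far
    rarefaction-based richness estimates undershoot. Includes synthetic
    survey, mesocosm time-series and Yule-process community generators with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
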