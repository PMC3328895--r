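Package: tearfilm
Title: Colour-Texture Classification of Tear Film Lipid Layer Interference Patterns
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automatic categorisation of tear film lipid layer interference
    patterns into the Guillon grades (open meshwork, closed meshwork, wave,
    colour fringe) from eye photographs. Provides region-of-interest
    extraction by normalised cross-correlation against illumination
    templates, five colour-texture descriptor families (Butterworth band
    histograms, Haar wavelet statistics, grey-level co-occurrence and
    Haralick features, Gaussian Markov random field directional variances,
    Gabor filter bank histograms) computed in grayscale, CIE Lab and
    opponent colour spaces, five classifier families evaluated by
    stratified 10-fold cross-validation, and a classifier-comparison
    workflow (Lilliefors normality gate, one-way ANOVA, Tukey HSD).
    Includes a seeded synthetic-image generator emulating the four
    categories so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
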