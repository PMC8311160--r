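Package: ramandrought
Title: Raman Spectral Phenotyping of Drought Stress via Carotenoid Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies drought-induced carotenoid degradation from in vivo leaf
    Raman spectra. Implements the three-stage spectral preprocessing used for
    plant tissue (iterative-polynomial "modified polyfit" fluorescence baseline
    removal, Savitzky-Golay smoothing, unit-vector normalization), carotenoid
    band quantification at 1007/1157/1524 cm-1, hyperspectral band-intensity
    mapping of mannitol osmotic-stress time series, and a replicate-level
    relative degradation-rate estimator with one-way ANOVA group comparison for
    ranking genotypes by drought tolerance. Ships a synthetic leaf-spectrum
    generator (Lorentzian bands over an autofluorescence background) that
    emulates the full genotype x treatment x day study design and mannitol map
    series, so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
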