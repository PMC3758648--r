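Package: specmicro
Title: Characterization and Comparison of Hyperspectral Fluorescence
    Microscopy Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for characterizing hyperspectral fluorescence
    microscopy systems. Provides flat spectral correction of image cubes
    against dark/bright calibration acquisitions and a traceable lamp
    spectrum, construction of endmember spectral libraries from
    single-fluorophore controls, per-pixel linear spectral unmixing with
    root-mean-square error metrics, replicate-based signal-to-noise and
    coefficient-of-variation characterization, photobleaching decay-rate
    analysis, and spike-in theoretical sensitivity and specificity studies.
    Includes a synthetic acquisition simulator with widefield-EMCCD and
    confocal-PMT detector noise models so that every analysis stage can be
    exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
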