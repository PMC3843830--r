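Package: aviomt
Title: Ocular Media Transmittance and Ultraviolet Colour Vision in Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the ultraviolet transparency of bird ocular
    media and its consequences for colour vision. Implements spectral
    processing of transmittance curves (running-average smoothing, range
    normalisation, the 50%-transmittance wavelength and cut-off slope
    metrics), visual pigment absorbance templates screened by ocular media,
    receptor-noise-limited modelling of colour-discrimination thresholds for
    ultraviolet stimuli in di- to tetrachromatic visual systems, comparative
    statistics across species groups with Dunn-Sidak correction, curve
    fitting for eye-size relationships, and seeded generators of synthetic
    transmittance spectra and species tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Collate: 
    'utils.R'
    'AllClasses.R'
    'aviomt-package.R'
    'spectra-io.R'
    'synth.R'
    'stats.R'
    'visual-system.R'
    'rnl.R'
    'pipeline.R'
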