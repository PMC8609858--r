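Package: fluosignal
Title: Chlorophyll Fluorescence as a Density-Dependent Light Signal in
    Diatom Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the chlorophyll fluorescence photon flux exchanged
    between marine diatom cells: calibration of the per-cell emitted flux
    from a bulk culture measurement, the inverse-square pairwise model, the
    attenuated mean-field population integral with its closed form, and a
    discrete-cell Monte Carlo oracle. Also provides the supporting
    photophysiology formulas (Fv/Fm, Y(II), NPQ, rETR, de-epoxidation
    state), emission-spectrum band integration, and an iron-stratified
    Pearson correlation procedure for station tables of ISIP transcript
    shares versus chlorophyll content, together with seeded synthetic-data
    generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
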