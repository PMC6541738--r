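Package: duotune
Title: Synthetic Low-Noise Gene Expression Circuits and Cytometry Noise Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single-cell populations of bicistronic autoregulated
    (TetR- or LacI-type) plasmid expression circuits, renders them as flow
    cytometry event tables and fluorescence microscopy images, and analyses
    them with a density-gating / log-binned gamma-fitting pipeline:
    2D scatter density gating, probability densities on log-spaced bins,
    least-squares gamma fits, background-subtracted means and CV-squared
    noise, dose-response and plasmid-backbone comparisons, two-channel
    induction crosstalk, and single-mRNA spot signal-to-background scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    yaml,
    jsonlite,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
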