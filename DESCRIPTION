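Package: focusq
Title: Quantification of Fluorescent Puncta and Foci in Multi-Channel Cell Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for quantifying the spatial organization and
    colocalization of fluorescently labelled structures (puncta and foci, e.g.
    LC3B-positive membranes) in multi-channel 2D fluorescence microscopy fields.
    Provides background subtraction, watershed single-cell segmentation,
    blur-divide intensity equalization for structure segmentation, per-structure
    colocalization positivity scoring, per-cell Pearson correlation with
    hierarchical well-plate aggregation, radial dispersion profiles around the
    intensity-weighted centroid, relative gene expression from qPCR Ct tables
    (2^-ddCt), and a synthetic-image generator with planted ground truth so the
    whole pipeline can be exercised and validated without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
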