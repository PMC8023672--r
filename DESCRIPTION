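Package: imcviz
Title: Visualization and Gating of Highly Multiplexed Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel- and cell-level visualization for highly multiplexed
    imaging such as imaging mass cytometry. Colours segmentation masks by
    per-cell marker expression or metadata, blends up to six channels into
    RGB composites, outlines cells for segmentation quality control, ranks
    images by cell-type density, and performs hierarchical interval gating
    with image-backed verification and selection export. Includes a seeded
    synthetic-data generator with planted ground truth so every operation is
    testable offline, plus command entry points for rendering, gating,
    measurement and fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
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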