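Package: olfactr
Title: Odorant Receptor De-Orphanization Analysis for Insect Olfaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for functional characterization
    (de-orphanization) of insect odorant receptors. Quantifies odor
    responses from single-sensillum recordings (spike-count differences,
    solvent subtraction, spontaneous activity), computes tuning-breadth
    statistics (lifetime sparseness, response classification,
    dose-response summaries), processes calcium-imaging movies of the
    antennal lobe (delta F/F, photobleaching correction, spatial median
    filtering, rigid movement correction, glomerular response
    extraction), relates receptor response profiles to glomerular
    profiles (Spearman correlation mapping, ANOSIM, NMDS,
    knockout-versus-control comparison), and models the molecular
    consequence of splice-junction-disrupting deletions (exon skipping,
    transcript and protein arithmetic). A synthetic-data module
    generates every input with known ground truth so the full pipeline
    is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    vegan,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
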