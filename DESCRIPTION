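Package: meoct
Title: Speckle-Variance Angiography and Quantitative Analysis of Middle-Ear OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of handheld optical coherence
    tomography (OCT) of the middle ear. Implements speckle-variance OCT
    angiography from repeated B-scans, landmark-referenced cross-section
    extraction and en-face projection, region-of-interest intensity-ratio
    quantification normalized to the tympanic membrane and malleus lateral
    process, refractive-index depth calibration, tumor-to-membrane gap
    measurement, and two-sample group statistics computed from raw ratios or
    published summary statistics. Ships a synthetic middle-ear phantom
    generator with coherent speckle and flow-dependent temporal decorrelation,
    with voxel-level ground truth, emulating normal ears and three classes of
    middle-ear mass (glomus tumor, cholesteatoma, facial nerve schwannoma).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
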