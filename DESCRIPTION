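Package: ccfv
Title: Choriocapillaris Flow Voids and Geographic Atrophy Growth from En
    Face OCT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies choriocapillaris flow voids on en face optical
    coherence tomography angiography (OCTA), measures geographic atrophy
    (GA) growth between visits with the square-root-area transform, and
    estimates the pixel-level association between baseline flow voids and
    subsequent atrophy conversion using bias-reduced (Firth) logistic
    regression, with cluster-permutation inference that respects the
    pairing of two eyes within a patient.  Includes a synthetic-scene
    generator with a known logistic conversion law so that every stage of
    the pipeline can be validated against ground truth without patient
    scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
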