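Package: olagr
Title: Label-Free OCT Lymphangiography and Microangiography of Skin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for volumetric optical coherence tomography (OCT)
    of skin that maps blood vessels by optical microangiography (OMAG, speckle
    decorrelation across repeated B-frames) and lymphatic vessels by OCT-based
    lymphangiography (OLAG, attenuation compensation, epidermis/dermis
    segmentation, en-face histogram equalization and sorted minimum intensity
    projection). Includes a synthetic layered skin-phantom generator with
    voxel-level ground truth, vessel-density quantification, mosaicking of
    en-face tiles, TIFF+JSON volume input/output and a reproducible pipeline
    driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
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
RoxygenNote: 7.3.3
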