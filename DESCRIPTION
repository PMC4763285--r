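Package: microcolony
Title: Lensless On-Chip Microcolony Counting by Sub-Pixel Sweeping Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of real-time bacterial microcolony
    counting on a lensless on-chip (shadow-imaging) microscopy platform.
    Provides a forward simulator of growing colony phantoms imaged by a
    pixel array under a sweeping illumination source, shift-and-add pixel
    super-resolution reconstruction with digital refocusing, edge-based
    colony segmentation with equivalent-diameter sizing, time-lapse colony
    tracking with merge bookkeeping, and enumeration statistics (count
    saturation, titer estimation, exact Mann-Whitney comparison of assays).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
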