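Package: podonano
Title: Nanoscale Morphometry and Dynamics of Osteoclast Sealing-Zone Actin Cores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image analysis of the actin cores that compose the
    osteoclast sealing zone and podosome belt. Provides detection of actin
    cores on super-resolution frames with radial-derivative radius estimation,
    Delaunay-tessellation neighbor morphometrics with convex-hull edge
    exclusion, time-lapse synchrony and Fourier periodicity analysis,
    two-color line-profile and islet analysis, signed radial-axial analysis of
    3D single-molecule localizations, and a seeded synthetic-data generator
    that emulates the statistical structure of sealing-zone imaging data so
    that every stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deldir,
    tiff,
    jsonlite,
    EBImage,
    igraph,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
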