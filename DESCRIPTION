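Package: gridcodes
Title: Coordinate-Encoding Fiducial Microgrids for Correlative Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Design, simulation and machine reading of coordinate-encoding
    fiducial microgrids for multimodal and correlative microscopy. Encodes
    integer grid coordinates into microfabricatable marker geometries
    (binary, ternary, decimal and postal two-of-five bar schemes), places
    them on a pitch chosen from the bottleneck instrument's field of view,
    and exports GDSII photomask layouts. A parametric camera model renders
    synthetic brightfield/darkfield/SEM-like images of the grids with
    ground truth; a classical machine-vision decoder recovers coordinates,
    sub-pixel positions and orientation from such images. Two-anchor
    calibration maps grid coordinates to instrument stage coordinates and
    reports substrate-deformation scale factors; fiducial correspondences
    drive least-squares co-registration and overlay of multimodal image
    pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
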