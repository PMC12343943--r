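Package: cinemr
Title: Convert 1.5 T MR-Linac 2D Cine MR Frames from Vendor Binary Format to
    MHA and DICOM with Motion QA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with 2D cine magnetic-resonance frames recorded
    during MR-guided radiotherapy on a 1.5 T MR-linac and stored in a
    proprietary headered binary format. The package decodes the binary frame
    dialect (4,084-byte opaque header plus little-endian unsigned 16-bit
    pixels), reads the acquisition-geometry and target-centroid JSON sidecars,
    orders frames by millisecond timestamps, classifies each frame's imaging
    plane (coronal, sagittal, axial) from its corner intensity signature,
    applies the 22-pixel centering shift, assigns 3D patient-space geometry so
    the image center coincides with the target centroid, and serializes frames
    to MetaImage (MHA) and DICOM. Companion motion-QA routines measure phantom
    dimensions by half-maximum edge profiles, track target centroids,
    estimate periodic motion amplitudes, and recover translations by
    correlation-based subpixel registration. A deterministic synthetic fixture
    generator renders a motion-management QA phantom with programmed motion
    and writes byte-exact sessions, serving as the normative test oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    broom,
    jsonlite,
    tibble,
    dplyr,
    ggplot2,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
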