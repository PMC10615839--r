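Package: panoct
Title: Scan Geometry, Optical Biometry and Lesion Morphometry for Wide-Field Panretinal OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for ultra-wide-field (panretinal) optical
    coherence tomography of the infant eye. Models the globe as an ideal
    sphere with a configurable scanning pivot to convert between
    pivot-referenced and eye-center-referenced fields of view, predict
    required imaging depth and iris vignetting, and calibrate the field of
    view against a ringed phantom eye. Implements a Gullstrand schematic
    newborn eye for converting optical path length to geometric axial
    length, closed-form scan-protocol calculators (acquisition time, axial
    resolution, sampling-limited depth, focal spot size), a seeded
    generator of synthetic fan-beam OCT volumes with speckle and
    sensitivity roll-off, an axial-length biometry pipeline driven by
    reference-arm stage positions, and curvature-aware tumor morphometry
    (sphere fitting, elevation mapping, geodesic length/width/height).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    tiff,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
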