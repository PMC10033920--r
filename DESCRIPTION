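Package: DicomSlide
Title: Whole-Slide Microscopy Pyramids, Pixel Transformations and ROI
    Annotations for DICOM
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A headless toolkit for digital pathology images stored in
    DICOM format. Assembles multi-resolution pyramids of tiled VL Whole
    Slide Microscopy Image instances from metadata alone (TILED_FULL,
    TILED_SPARSE and concatenated instances), maps 2D total-pixel-matrix
    coordinates to 3D slide coordinates in millimeters via affine
    transforms, and executes the DICOM pixel transformation sequences:
    ICC profile connection space color management for brightfield images,
    VOI windowing, (segmented) palette color lookup tables and additive
    blending for multiplexed immunofluorescence channels, and alpha
    compositing of analysis-result overlays. Encodes and decodes Advanced
    Blending Presentation States, Comprehensive 3D SR measurement reports
    (SCOORD3D regions of interest with coded evaluations and UCUM
    measurements), Microscopy Bulk Simple Annotations, Segmentations and
    Parametric Maps with real-world value mappings. Includes a uniform
    query/retrieve/store interface over local DICOM file stores and
    DICOMweb services, and a deterministic synthetic-fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    jsonlite,
    grDevices,
    stats,
    utils,
    png,
    jpeg
Suggests:
    curl,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'dicom-dict.R'
    'dicom-io.R'
    'dicom-json.R'
    'datamodel.R'
    'geometry.R'
    'pixels.R'
    'icc.R'
    'rendering.R'
    'store.R'
    'pyramid.R'
    'presentation.R'
    'annotations.R'
    'annotations-convert.R'
    'overlays.R'
    'fixtures.R'
    'cli.R'
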