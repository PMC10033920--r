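# DicomSlide

Digital pathology increasingly stores whole-slide microscopy images in
DICOM: each resolution level of a scanned slide is one *VL Whole Slide
Microscopy Image* object whose pixel matrix is split into tiled frames,
and annotations, display settings and analysis results travel alongside
as standard DICOM objects. DicomSlide is an R toolkit for working with
these data headlessly — the computational core of a slide viewer,
without the viewer: pyramid assembly, coordinate geometry, the DICOM
pixel transformation sequences, and standards-conformant encoding and
decoding of the surrounding objects. It is aimed at image-analysis
pipelines, archive tooling and test harnesses that need to read,
render, measure and write slide-microscopy DICOM without a browser or
a commercial workstation.

## What it implements

**Pyramids from metadata.** Instances are grouped into digital slides
by frame of reference; the multi-resolution pyramid is determined
purely from structural metadata. Both `TILED_FULL` (implicit row-major
frame order) and `TILED_SPARSE` (explicit per-frame positions, missing
tiles allowed) organizations are supported, as are concatenations
(one level split across several instances). `readRegion()` mosaics
raw tile frames into arbitrary rectangles, filling missing tiles with
background and reporting a provenance mask.

**Geometry.** A single 3×3 homogeneous matrix maps sub-pixel image
coordinates (column, row) of the total pixel matrix to 3D slide
coordinates in millimeters,

    [x]   [ r_x·Δc   c_x·Δr   X_0 ] [column]
    [y] = [ r_y·Δc   c_y·Δr   Y_0 ] [row   ]
    [1]   [   0        0       1  ] [1     ]

with direction cosines (r, c), pixel spacings Δc, Δr and origin
(X₀, Y₀); the inverse is cached. Integer coordinate (0, 0) is the
*center* of the top-left pixel, which makes round trips exact.

**Pixel transformations.** True-color brightfield images pass through
the ICC profile connection space transform (matrix-shaper profiles,
built and parsed natively). Grayscale fluorescence channels pass
through VOI windowing

    y = clamp((x − (c − w/2)) / w, 0, 1),

a palette color LUT (explicit or segmented descriptors; index
`round(y·(L−1))`), and additive blending `clamp(Σ channels, 0, 255)`.
Overlays composite as `α·over + (1−α)·under`. Embedded palette LUTs
always win over user settings; the VOI window is always
user-adjustable.

**Standard objects.** Advanced Blending Presentation States (channel
selection + windows + segmented palette LUTs, with the three default
staining-target groups for nine-plex immunofluorescence panels);
Comprehensive 3D SR measurement reports (SCOORD3D regions in slide
millimeters with coded evaluations and UCUM measurements); Microscopy
Bulk Simple Annotations; binary and fractional Segmentations;
Parametric Maps with linear real-world value mappings and automatic
sequential/diverging colormap selection.

**Stores.** One interface, two backends: a local directory of Part-10
files with an on-disk index, and a DICOMweb client (QIDO-RS / WADO-RS
/ STOW-RS, multipart frame retrieval, pluggable transport with bearer
token support). The two are observationally equivalent, which the
test suite asserts.

**Fixtures.** A deterministic generator produces conformant synthetic
studies — brightfield pyramids with embedded ICC profiles, 16-bit
multiplexed fluorescence channels with coded staining targets, sparse
and concatenated variants, and derived analysis objects — retaining
ground truth for byte-exact assertions. No downloads are needed
anywhere.

## Worked example

```r
library(DicomSlide)

# a complete synthetic study set in a local store
store <- writeFixtureStore(file.path(tempdir(), "demo"), seed = 7,
                           baseSize = 256, tileSize = 128)
cmdSlidesList(store)
#>                                 identifier channels levels labels overviews
#> 1   1.2.826.0.1.3680043.10.1081.33684305.3        1      2      1         1
#> 2 1.2.826.0.1.3680043.10.1081.427562520.12        9      1      0         0
```

Two slides: a brightfield pyramid (2 levels, label and overview
images) and a nine-channel fluorescence slide. Windowing a stored
value of 900 with center 1000 and width 400 places it a quarter of
the way up the ramp:

```r
applyVoi(900, voiWindow(1000, 400))
#> [1] 0.25
```

Drawing a 1000×1000-pixel square on the base level (0.25 µm pixels)
and measuring it in slide space:

```r
slide <- ...  # from groupSlides(); see vignette
map <- pyramidAffineMap(slide)
g <- roiFromPixels("POLYGON",
                   cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)),
                   map, frameOfReference = slide@frame_of_reference_uid)
for (m in measureRoi(g)) cat(m@name@meaning, m@value, m@unit@value, "\n")
#> Area 0.0625 mm2
#> Perimeter 1 mm
```

A 0.25 mm × 0.25 mm square: area 0.0625 mm², perimeter 1 mm, with
UCUM-coded units ready for an SR measurement report
(`encodeMeasurementReport()`).

A shell entry point wraps the same functions:

```sh
inst/cli/dicomslide fixtures-generate --store /tmp/demo --seed 7
inst/cli/dicomslide slides-list --store /tmp/demo
inst/cli/dicomslide render --store /tmp/demo --slide <id> \
    --region 0,0,256,256 --out region.png
```

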