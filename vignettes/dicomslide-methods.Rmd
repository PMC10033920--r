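---
title: "Methods: pyramids, pixel transformations and annotations in DicomSlide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pyramids, pixel transformations and annotations in DicomSlide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DicomSlide)
```

This vignette documents the models, conventions and numerical choices
behind DicomSlide in one place, the way an analysis package documents
its statistics: what is computed, under which assumptions, which knobs
exist, and what the synthetic test bed does and does not establish.

## The data model

A scanned slide is stored as a set of DICOM VL Whole Slide Microscopy
Image instances sharing one *frame of reference*: one instance per
resolution level (and, for multiplexed fluorescence, per channel),
each a multi-frame object whose frames tile the level's *total pixel
matrix*. `parseImageMetadata()` reduces an instance to the structural
fields every other module consumes (`SlideImageMetadata`); parsing is
identical for Part-10 input and DICOM JSON metadata resources, and is
order-independent in the JSON representation.

Conventions adopted where the standard leaves latitude:

* **Flavor** is the third value of Image Type. Unknown flavors map to
  VOLUME with a warning rather than failing: a viewer should show an
  unfamiliar image, not refuse the slide. THUMBNAIL is treated as
  OVERVIEW.
* **UIDs are opaque strings**; no semantics are read out of them.
* Single-frame label and overview images are modeled as a 1×1 tile
  grid, so every image flows through the same tiling code.
* Staining substances are read from TID 8001-style specimen
  preparation items whose concept name is "Using substance"
  (SCT 424361007). A malformed specimen sequence degrades to an empty
  target list with a warning, because staining metadata is advisory,
  not structural.

## Pyramid assembly

Levels are recognized purely from metadata: instances are grouped by
(study, frame of reference), channels by optical path identifier,
concatenation partners are merged (frame offsets shifting their tile
numbering), and levels are ordered by descending total width with SOP
Instance UID as a deterministic tie-break. Downsampling factors are
the float ratios `base_total_cols / level_total_cols` — no
power-of-two assumption, and a *missing* level simply leaves a gap in
the factor sequence.

Each level's physical extent (total size × pixel spacing) must match
the base level within a relative tolerance of **1e-2**. Scanners
round spacings per level, so exact equality is wrong; beyond one
percent the instance more plausibly belongs to a different slide, and
assembly fails naming it.

Tile grids: `TILED_FULL` frames are enumerated row-major
(`frame = tile_row · grid_cols + tile_col + 1`); `TILED_SPARSE`
positions must land exactly on the tile grid (anything else is a
corrupt object, reported as an alignment error). Missing sparse tiles
are filled at read time with **255 per sample for RGB brightfield**
(white glass — the empty slide background) and **0 for monochrome
fluorescence** (no signal), and the provenance mask distinguishes
filled from fetched pixels so downstream quantification can exclude
them. Edge tiles may extend past the declared matrix and are cropped.

`selectLevel()` returns the coarsest level whose spacing does not
exceed the requested mm-per-pixel, falling back to the finest level —
the choice that never renders at worse than the requested resolution.

## Coordinate geometry

The forward map is one homogeneous 3×3 matrix built from the
*highest-resolution* image's orientation cosines, pixel spacings and
origin; z is carried as a constant plane offset. The inverse is
computed once and cached; construction fails if the cosine triplets
are parallel.

The **pixel-center convention** is the load-bearing choice: integer
coordinate (0, 0) denotes the center of the top-left pixel and the
metadata origin is that center's slide position. Under this
convention pixel→slide→pixel round trips are exact up to floating
point (measured worst case around 1e-10 px over randomized maps —
well under the 1e-6 px contract), and coordinates stored in slide
space are valid for every level and channel: the tests map drawn
points through two different levels' own maps and land within half a
base pixel. All arithmetic is in R doubles; the 32-bit-float minimum
the rendering contract requires is exceeded throughout. Stored
SCOORD3D points use the image's z offset when a focal plane is
present and 0 otherwise; focal-stack navigation itself is out of
scope.

## The display pipeline

Grayscale chain, evaluated per pixel in double precision with one
quantization at the end:

1. **VOI window** `y = clamp((x − (c − w/2))/w, 0, 1)`. This is the
   plain clip-and-rescale form; the historical variant with the
   `w − 1` denominator is available as `variant = "legacy"`. The two
   differ by at most one part in `w`; the exact form is the default
   because its window edges map exactly to 0 and 1.
2. **Palette color LUT** with index `round(y · (L − 1))`, rounding
   half away from zero, so `y = 1` reaches the last entry and the
   maximum attainable display value equals the maximum table entry
   (255 for a full ramp). Segmented descriptors expand with discrete
   segments repeating their value and linear segments interpolating
   from the previous entry — two segments suffice for a ramp.
   16-bit embedded tables are rescaled to 8-bit display values
   (divide by 257), an assumption recorded here because the encoding
   does not state the display depth.
3. **Additive blending** `clamp(Σ, 0, 255)` — commutative, and inert
   under all-zero channels.

Precedence: an image-embedded palette LUT always wins and cannot be
overridden (the producer's rendering intent is part of the data); a
presentation-state LUT beats ad-hoc user settings; the VOI window
remains user-adjustable always.

**Color management.** Brightfield rendering transforms device RGB
through the ICC profile connection space (D50 CIEXYZ): linearize with
the input profile's tone curves, matrix to XYZ, inverse-matrix and
re-encode with the display profile (default sRGB-targeting, gamma
2.2, D50-adapted primaries; rendering intent is recorded and
configurable, with identical results for matrix profiles sharing a
white point). Profiles are parsed natively; only matrix-shaper
profiles (XYZ primaries + gamma curves) are supported and LUT-based
profiles raise a profile error — the synthetic profiles the package
constructs (`createIccProfile()`: srgb / identity / swapped-primaries
/ wide-gamut) are matrix profiles precisely so that expected outputs
are analytically predictable. Out-of-gamut PCS values clip in
display-linear space. Images without an embedded profile render raw
with a logged notice.

**Overlays.** Segmentation fractions map to [0, 1] as
`stored / MaximumFractionalValue` (the declared maximum is honored
even though the common case is 255). Parametric maps apply their
real-world value LUT (`real = slope · stored + intercept`, or an
explicit table); the default colormap is chosen from the real bounds
— **viridis** when one-signed, **blue–white–red diverging centered at
0 with symmetric range max(|lower|, |upper|)** when the bounds cross
zero; the diverging palette is this package's choice where only
"a diverging colormap" is prescribed. Colorbars default to 5 evenly
spaced ticks. When an analysis object's grid differs from the display
level, alignment goes through both objects' affine maps with
nearest-neighbor resampling — interpolating class probabilities
between pixels would invent data. Compositing multiplies the overlay
alpha by the user's opacity and rounds half away from zero.

## Annotations

ROIs drawn in image space are transformed to SCOORD3D slide
millimeters through the base-level map before storage, making them
resolution- and channel-independent. Point-count rules follow the
graphic types (polygons auto-close with a notice). Size measurements
are the package's documented choice: polygons get shoelace area and
perimeter; ellipses get `πab` and Ramanujan's circumference
approximation; polylines get length; points get none. Coordinates are
serialized at full float precision — "millimeter" is the unit, not a
rounding.

SR documents follow the measurement-report template shape: one
container per ROI with tracking identifier and UID, the SCOORD3D
region, optional coded finding, coded evaluations and UCUM-coded
numeric measurements; the observer identity is carried in observation
context. Decoding is tolerant: unknown content items are preserved as
opaque extras (the template is extensible) and a group missing its
geometry is skipped with a warning while the rest of the document
parses. Question/answer code sets constrain evaluations so readers
never enter free text; the shipped set uses placeholder codes under a
private scheme ("99DSL") because no canonical code list is published
— deployments should substitute their own, and matching is on
(value, scheme) only.

Rasterization (contour → segmentation) marks a pixel foreground iff
its **center** lies inside the polygon under the even-odd rule, with
centers exactly on an edge counted inside; the suite checks this
against an independently written point-in-polygon oracle. Bulk
annotation groups store coordinates in flat 32-bit float arrays with
1-based value indices marking item starts, and per-ROI measurement
vectors whose length must equal the annotation count.

## The store layer

The local backend is a directory of Part-10 files plus a JSON index
(rebuilt by scanning when absent). The DICOMweb backend implements
the search/retrieve/store transactions over a pluggable transport
function; the default transport uses the curl package, and
`dicomwebHandler()` provides an in-process transport that serves a
local store — the test suite drives the complete client path (URL
construction, DICOM JSON, multipart parsing, STOW receipts) through
it and asserts observational equivalence with the local backend.
Authentication is a bearer-token callback injected per request;
paging uses `offset`/`limit` query parameters (a documented choice —
the transaction standard leaves paging to the service). Frame
numbering is 1-based everywhere; no public API exposes 0-based frame
indices. Multiple stores with roles (`images`, `annotations-read`,
`annotations-write`) allow the common deployment where a read-only
image archive is paired with a writable annotation store.

The package writes Explicit VR Little Endian, with encapsulated pixel
data for JPEG-compressed frames. Uncompressed
("application/octet-stream") and JPEG ("image/jpeg") frames encode
and decode; "image/jp2", "image/jpx" and "image/jls" are recognized
in negotiation but raise a structured error on decode, as no JPEG
2000 or JPEG-LS codec is available to R here — lossless-codec
round-trip behavior is therefore exercised with uncompressed frames,
and JPEG is covered by near-equality bounds. Implicit VR input is
rejected rather than guessed at. The Part-10 writer is cross-checked
against pydicom in the test suite.

## The synthetic test bed

`writeFixtureStore()` builds the study conditions all tests and the
acceptance script run under: a brightfield pyramid (256-px base, two
levels at factors 1 and 4, 128-px tiles, 0.25 µm base spacing,
identity ICC profile, H&E staining codes) and a nine-channel
fluorescence slide (16-bit, 0.325 µm spacing, one series per channel,
the nine default staining targets, disjoint Gaussian blobs with
retained masks), plus derived SR / bulk / segmentation / parametric
map objects. Individual tests scale geometry up or down (64–1024 px)
where a property needs it; these sizes keep the full suite under a
minute while every code path — sparse, concatenated, compressed,
multichannel — is exercised. Pyramid levels are built by block
averaging, which is also the reference the level-consistency check
compares against, so that property is exact here (MAE 0 ≤ 2 codes)
rather than an approximation as it would be on scanner output.
Timestamps are fixed to a sentinel date and UIDs come from a seeded
Lehmer-sequence factory, making generation byte-reproducible; in
production use the factory seeds from the clock and process id.

What the fixtures do **not** emulate: realistic tissue texture,
scanner-specific metadata quirks and private attributes, vendor ICC
profiles with sampled tone curves or cLUTs, focal stacks, and lossy
codecs other than baseline JPEG. Passing tests establish standards
conformance and numerical correctness of the transforms on exact,
known inputs — not robustness to malformed vendor output.

## Known limitations

* No JPEG 2000 / JPEG-LS codecs; no SIGMOID VOI function; no
  Grayscale Softcopy Presentation States; no 2D SCOORD annotations.
* Full-instance retrieval (pixel data included) is implemented for
  local stores; over DICOMweb the client retrieves metadata and
  frames, which covers rendering but not re-export of foreign
  instances.
* Binary segmentation frames are bit-packed per frame (each frame
  padded to a byte boundary); tile sizes whose pixel count is a
  multiple of 8 — the universal case — are unaffected by the padding.
* The default per-channel VOI window in generated presentation states
  is the full stored range: deterministic and safe, but not
  contrast-optimal; an external window estimator can be supplied via
  the `windows` hook of `defaultStainingGroups()`.
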