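#' @import methods
NULL

# ---- CodedConcept -----------------------------------------------------

#' Coded concept (code value, coding scheme, meaning)
#'
#' The triplet used throughout DICOM to encode machine-readable
#' concepts: a code value, the designator of the coding scheme the value
#' comes from (e.g. "SCT", "DCM", "UCUM"), and a human-readable meaning.
#' Equality of two concepts is defined on (value, scheme) only — the
#' meaning is display text and never participates in comparisons.
#'
#' @slot value Code value (non-empty string).
#' @slot scheme Coding scheme designator (non-empty string).
#' @slot meaning Human-readable code meaning.
#' @export
setClass("CodedConcept", representation(
  value = "character", scheme = "character", meaning = "character"
))

setValidity("CodedConcept", function(object) {
  if (length(object@value) != 1L || !nzchar(object@value))
    return("code value must be a non-empty string")
  if (length(object@scheme) != 1L || !nzchar(object@scheme))
    return("coding scheme designator must be a non-empty string")
  TRUE
})

#' @param value,scheme,meaning See slots.
#' @rdname CodedConcept-class
#' @examples
#' a <- CodedConcept("14885008", "SCT", "Vimentin")
#' b <- CodedConcept("14885008", "SCT", "vimentin protein")
#' codedEqual(a, b)   # TRUE: meaning is ignored
#' @export
CodedConcept <- function(value, scheme, meaning = "") {
  new("CodedConcept", value = as.character(value),
      scheme = as.character(scheme), meaning = as.character(meaning))
}

#' Compare coded concepts on (value, scheme)
#' @param a,b `CodedConcept`s.
#' @return Logical.
#' @export
codedEqual <- function(a, b) {
  a@value == b@value && a@scheme == b@scheme
}

setMethod("show", "CodedConcept", function(object) {
  cat(sprintf("<%s, %s, \"%s\">\n", object@value, object@scheme,
              object@meaning))
})

# ---- SlideImageMetadata ----------------------------------------------

#' Per-instance whole-slide image metadata
#'
#' The structural metadata of one VL Whole Slide Microscopy Image
#' instance needed for pyramid assembly, coordinate geometry and
#' rendering: identifiers, image flavor (VOLUME / LABEL / OVERVIEW),
#' total pixel matrix and tile dimensions, photometric and bit-depth
#' description, pixel spacing and slide-coordinate origin/orientation,
#' dimension organization (TILED_FULL or TILED_SPARSE with explicit
#' per-frame positions), concatenation linkage, optical paths, coded
#' staining targets, and optional embedded ICC profile / palette LUT.
#'
#' @slot study_uid,series_uid,sop_instance_uid,frame_of_reference_uid UIDs.
#' @slot flavor One of "VOLUME", "LABEL", "OVERVIEW".
#' @slot total_rows,total_cols Total pixel matrix size (pixels).
#' @slot tile_rows,tile_cols Frame (tile) size (pixels).
#' @slot num_frames Number of frames in this instance.
#' @slot samples_per_pixel,bits_allocated,bits_stored Pixel format.
#' @slot photometric Photometric interpretation string.
#' @slot pixel_spacing_row_mm,pixel_spacing_col_mm mm per pixel.
#' @slot origin_x_mm,origin_y_mm,origin_z_mm Slide-coordinate position of
#'   the center of pixel (row 0, column 0).
#' @slot orientation Six direction cosines (row triplet then column triplet).
#' @slot dimension_organization "TILED_FULL" or "TILED_SPARSE".
#' @slot concatenation_uid,concatenation_frame_offset Concatenation linkage
#'   (`NA`/`NA_integer_` when the instance is not part of one).
#' @slot per_frame_positions Integer matrix (n x 2: row, col 0-based pixel
#'   offsets of each frame in the total pixel matrix); required exactly
#'   when TILED_SPARSE.
#' @slot optical_paths data.frame(identifier, description, wavelength).
#' @slot staining_targets List of [CodedConcept-class] staining targets.
#' @slot icc_profile Raw ICC profile bytes (length 0 when absent).
#' @slot palette_lut A `PaletteColorLut` or `NULL`.
#' @slot transfer_syntax_uid Transfer syntax of the stored pixel data.
#' @export
setClass("SlideImageMetadata", representation(
  study_uid = "character", series_uid = "character",
  sop_instance_uid = "character", frame_of_reference_uid = "character",
  flavor = "character",
  total_rows = "numeric", total_cols = "numeric",
  tile_rows = "numeric", tile_cols = "numeric",
  num_frames = "numeric",
  samples_per_pixel = "numeric", bits_allocated = "numeric",
  bits_stored = "numeric", photometric = "character",
  pixel_spacing_row_mm = "numeric", pixel_spacing_col_mm = "numeric",
  origin_x_mm = "numeric", origin_y_mm = "numeric", origin_z_mm = "numeric",
  orientation = "numeric",
  dimension_organization = "character",
  concatenation_uid = "character",
  concatenation_frame_offset = "numeric",
  per_frame_positions = "ANY",
  optical_paths = "data.frame",
  staining_targets = "list",
  icc_profile = "raw",
  palette_lut = "ANY",
  transfer_syntax_uid = "character"
))

setValidity("SlideImageMetadata", function(object) {
  msgs <- character(0)
  for (f in c("total_rows", "total_cols", "tile_rows", "tile_cols",
              "num_frames"))
    if (slot(object, f) < 1) msgs <- c(msgs, sprintf("%s must be >= 1", f))
  if (object@pixel_spacing_row_mm <= 0 || object@pixel_spacing_col_mm <= 0)
    msgs <- c(msgs, "pixel spacings must be > 0")
  if (!object@flavor %in% c("VOLUME", "LABEL", "OVERVIEW"))
    msgs <- c(msgs, "flavor must be VOLUME, LABEL or OVERVIEW")
  if (!object@dimension_organization %in% c("TILED_FULL", "TILED_SPARSE"))
    msgs <- c(msgs, "dimension organization must be TILED_FULL or TILED_SPARSE")
  sparse <- identical(object@dimension_organization, "TILED_SPARSE")
  has_pos <- !is.null(object@per_frame_positions)
  if (sparse != has_pos)
    msgs <- c(msgs, "per_frame_positions present iff TILED_SPARSE")
  if (length(object@orientation) != 6) {
    msgs <- c(msgs, "orientation must hold six direction cosines")
  } else {
    n1 <- sqrt(sum(object@orientation[1:3]^2))
    n2 <- sqrt(sum(object@orientation[4:6]^2))
    if (abs(n1 - 1) > 1e-4 || abs(n2 - 1) > 1e-4)
      msgs <- c(msgs, "orientation triplets must be unit-norm within 1e-4")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "SlideImageMetadata", function(object) {
  cat(sprintf(
    "SlideImageMetadata %s\n  flavor %s, %.0fx%.0f px, tiles %.0fx%.0f, %d frames, %s, %s\n",
    object@sop_instance_uid, object@flavor, object@total_rows,
    object@total_cols, object@tile_rows, object@tile_cols,
    as.integer(object@num_frames), object@photometric,
    object@dimension_organization))
})

# Accessors (slot access is internal; these are the public surface).

#' Accessors for SlideImageMetadata
#' @param x A `SlideImageMetadata`.
#' @return The corresponding field.
#' @name metadata-accessors
NULL

#' @rdname metadata-accessors
#' @export
imageFlavor <- function(x) x@flavor
#' @rdname metadata-accessors
#' @export
totalPixelMatrixRows <- function(x) x@total_rows
#' @rdname metadata-accessors
#' @export
totalPixelMatrixCols <- function(x) x@total_cols
#' @rdname metadata-accessors
#' @export
numFrames <- function(x) as.integer(x@num_frames)
#' @rdname metadata-accessors
#' @export
pixelSpacing <- function(x) c(row = x@pixel_spacing_row_mm,
                              col = x@pixel_spacing_col_mm)
#' @rdname metadata-accessors
#' @export
sopInstanceUID <- function(x) x@sop_instance_uid
#' @rdname metadata-accessors
#' @export
frameOfReferenceUID <- function(x) x@frame_of_reference_uid
#' @rdname metadata-accessors
#' @export
stainingTargets <- function(x) x@staining_targets
#' @rdname metadata-accessors
#' @export
opticalPaths <- function(x) x@optical_paths
#' @rdname metadata-accessors
#' @export
iccProfileBytes <- function(x) x@icc_profile

.require_attr <- function(ds, keyword) {
  if (!dcmHas(ds, keyword))
    dcmStop("missing_attribute",
            "required attribute %s (%s) is missing", keyword, dcmTag(keyword))
  dcmValue(ds, keyword)
}

#' Parse whole-slide image metadata from a DICOM dataset
#'
#' Accepts a Part-10 `DicomDataset` or a DICOM JSON model mapping (the
#' two parse identically). The third value of Image Type determines the
#' flavor; unknown flavors fall back to VOLUME with a warning. Single
#' frame non-tiled instances (labels, overviews) are modeled as a 1x1
#' tile grid.
#'
#' @param ds `DicomDataset`, or a named list in the DICOM JSON model.
#' @return A [SlideImageMetadata-class].
#' @export
parseImageMetadata <- function(ds) {
  if (!inherits(ds, "DicomDataset")) ds <- datasetFromJsonModel(ds)
  sop_class <- dcmValue(ds, "SOPClassUID", "")
  if (!identical(sop_class, SOP_VL_WSI))
    dcmStop("wrong_sop_class",
            "dataset is not a VL Whole Slide Microscopy Image (SOP class %s)",
            sop_class)
  .parseTiledImageMetadata(ds)
}

# Shared field extraction used for VL WSI, Segmentation and Parametric
# Map instances (all are tiled multi-frame objects on the slide).
.parseTiledImageMetadata <- function(ds) {
  image_type <- dcmValue(ds, "ImageType", character(0))
  flavor <- if (length(image_type) >= 3) image_type[3] else "VOLUME"
  if (!flavor %in% c("VOLUME", "LABEL", "OVERVIEW", "THUMBNAIL")) {
    dcmWarn("unknown_flavor",
            "unknown image flavor '%s'; treating as VOLUME", flavor)
    flavor <- "VOLUME"
  }
  if (flavor == "THUMBNAIL") flavor <- "OVERVIEW"

  rows <- .require_attr(ds, "Rows")
  cols <- .require_attr(ds, "Columns")
  total_rows <- dcmValue(ds, "TotalPixelMatrixRows", rows)
  total_cols <- dcmValue(ds, "TotalPixelMatrixColumns", cols)
  nframes <- as.integer(dcmValue(ds, "NumberOfFrames", 1L))

  shared <- dcmValue(ds, "SharedFunctionalGroupsSequence", list())
  spacing <- NULL
  if (length(shared) >= 1) {
    pm <- dcmValue(shared[[1L]], "PixelMeasuresSequence", list())
    if (length(pm) >= 1) spacing <- dcmValue(pm[[1L]], "PixelSpacing")
  }
  if (is.null(spacing)) spacing <- dcmValue(ds, "PixelSpacing")
  if (is.null(spacing))
    dcmStop("missing_attribute",
            "required attribute PixelSpacing (%s) is missing",
            dcmTag("PixelSpacing"))

  origin <- c(0, 0, 0)
  org_seq <- dcmValue(ds, "TotalPixelMatrixOriginSequence", list())
  if (length(org_seq) >= 1) {
    origin[1] <- dcmValue(org_seq[[1L]], "XOffsetInSlideCoordinateSystem", 0)
    origin[2] <- dcmValue(org_seq[[1L]], "YOffsetInSlideCoordinateSystem", 0)
    origin[3] <- dcmValue(org_seq[[1L]], "ZOffsetInSlideCoordinateSystem", 0)
  }
  orientation <- as.numeric(dcmValue(ds, "ImageOrientationSlide",
                                     c(1, 0, 0, 0, 1, 0)))

  org_type <- dcmValue(ds, "DimensionOrganizationType", "TILED_FULL")
  per_frame_positions <- NULL
  if (identical(org_type, "TILED_SPARSE")) {
    pfg <- dcmValue(ds, "PerFrameFunctionalGroupsSequence", list())
    if (length(pfg) != nframes)
      dcmStop("missing_attribute",
              "TILED_SPARSE instance lacks per-frame plane positions (%s)",
              dcmTag("PerFrameFunctionalGroupsSequence"))
    pos <- t(vapply(pfg, function(item) {
      pps <- dcmValue(item, "PlanePositionSlideSequence", list())
      if (length(pps) < 1)
        dcmStop("missing_attribute",
                "per-frame item lacks PlanePositionSlideSequence (%s)",
                dcmTag("PlanePositionSlideSequence"))
      c(dcmValue(pps[[1L]], "RowPositionInTotalImagePixelMatrix") - 1,
        dcmValue(pps[[1L]], "ColumnPositionInTotalImagePixelMatrix") - 1)
    }, c(0, 0)))
    per_frame_positions <- matrix(as.integer(pos), ncol = 2L,
                                  dimnames = list(NULL, c("row", "col")))
  }

  paths <- dcmValue(ds, "OpticalPathSequence", list())
  optical_paths <- if (length(paths)) {
    data.frame(
      identifier = vapply(paths, function(p)
        as.character(dcmValue(p, "OpticalPathIdentifier", "")), ""),
      description = vapply(paths, function(p)
        as.character(dcmValue(p, "OpticalPathDescription", "")), ""),
      wavelength = vapply(paths, function(p) {
        w <- dcmValue(p, "IlluminationWaveLength", NA_real_)
        as.numeric(w[1])
      }, 0),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(identifier = character(0), description = character(0),
               wavelength = numeric(0), stringsAsFactors = FALSE)
  }

  staining <- tryCatch(parseSpecimenStaining(ds), error = function(e) list())

  palette <- NULL
  pal_seq <- dcmValue(ds, "PaletteColorLookupTableSequence", list())
  if (length(pal_seq) >= 1) {
    palette <- tryCatch(.parsePaletteFromDataset(pal_seq[[1L]],
                                                 source = "embedded"),
                        error = function(e) NULL)
  } else if (dcmHas(ds, "RedPaletteColorLookupTableDescriptor")) {
    palette <- tryCatch(.parsePaletteFromDataset(ds, source = "embedded"),
                        error = function(e) NULL)
  }

  new("SlideImageMetadata",
      study_uid = .require_attr(ds, "StudyInstanceUID"),
      series_uid = .require_attr(ds, "SeriesInstanceUID"),
      sop_instance_uid = .require_attr(ds, "SOPInstanceUID"),
      frame_of_reference_uid = dcmValue(ds, "FrameOfReferenceUID", ""),
      flavor = flavor,
      total_rows = as.numeric(total_rows), total_cols = as.numeric(total_cols),
      tile_rows = as.numeric(rows), tile_cols = as.numeric(cols),
      num_frames = as.numeric(nframes),
      samples_per_pixel = as.numeric(.require_attr(ds, "SamplesPerPixel")),
      bits_allocated = as.numeric(.require_attr(ds, "BitsAllocated")),
      bits_stored = as.numeric(dcmValue(ds, "BitsStored",
                                        dcmValue(ds, "BitsAllocated"))),
      photometric = .require_attr(ds, "PhotometricInterpretation"),
      pixel_spacing_row_mm = as.numeric(spacing[1]),
      pixel_spacing_col_mm = as.numeric(spacing[2]),
      origin_x_mm = origin[1], origin_y_mm = origin[2], origin_z_mm = origin[3],
      orientation = orientation,
      dimension_organization = org_type,
      concatenation_uid = as.character(
        dcmValue(ds, "ConcatenationUID", NA_character_)),
      concatenation_frame_offset = as.numeric(
        dcmValue(ds, "ConcatenationFrameOffsetNumber", NA_real_)),
      per_frame_positions = per_frame_positions,
      optical_paths = optical_paths,
      staining_targets = staining,
      icc_profile = {
        prof <- NULL
        paths_seq <- dcmValue(ds, "OpticalPathSequence", list())
        if (length(paths_seq) >= 1)
          prof <- dcmValue(paths_seq[[1L]], "ICCProfile")
        if (is.null(prof)) prof <- dcmValue(ds, "ICCProfile")
        if (is.null(prof)) raw(0) else prof
      },
      palette_lut = palette,
      transfer_syntax_uid = dcmValue(ds, "TransferSyntaxUID",
                                     UID_EXPLICIT_VR_LE))
}

# Concept name used for staining-substance items in the specimen
# preparation sequence (TID 8001 style).
.code_using_substance <- function()
  CodedConcept("424361007", "SCT", "Using substance")

#' Extract coded staining targets from specimen metadata
#'
#' Walks the Specimen Description / Specimen Preparation sequences and
#' collects the coded substances of staining steps, in document order.
#' A malformed specimen sequence yields a warning and an empty list
#' rather than an error, since staining metadata is advisory.
#'
#' @param ds A `DicomDataset`.
#' @return List of [CodedConcept-class].
#' @export
parseSpecimenStaining <- function(ds) {
  if (!inherits(ds, "DicomDataset")) ds <- datasetFromJsonModel(ds)
  out <- list()
  descs <- dcmValue(ds, "SpecimenDescriptionSequence", list())
  for (desc in descs) {
    preps <- dcmValue(desc, "SpecimenPreparationSequence", list())
    for (prep in preps) {
      items <- dcmValue(prep, "SpecimenPreparationStepContentItemSequence",
                        list())
      for (item in items) {
        ok <- tryCatch({
          if (!identical(dcmValue(item, "ValueType", ""), "CODE")) {
            FALSE
          } else {
            name_seq <- dcmValue(item, "ConceptNameCodeSequence", list())
            if (length(name_seq) < 1) FALSE else {
              name <- codeFromItem(name_seq[[1L]])
              if (!codedEqual(name, .code_using_substance())) FALSE else {
                code_seq <- dcmValue(item, "ConceptCodeSequence", list())
                if (length(code_seq) < 1)
                  stop("staining item without concept code")
                out[[length(out) + 1L]] <- codeFromItem(code_seq[[1L]])
                TRUE
              }
            }
          }
        }, error = function(e) {
          dcmWarn("malformed_specimen",
                  "malformed specimen preparation item: %s",
                  conditionMessage(e))
          FALSE
        })
        invisible(ok)
      }
    }
  }
  out
}
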