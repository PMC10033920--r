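#' @title Deterministic synthetic DICOM fixtures
#'
#' @description Generates standards-conformant synthetic studies that
#'   exercise every code path — tiled multi-resolution true-color
#'   brightfield series with embedded matrix ICC profiles, 16-bit
#'   multichannel fluorescence series with coded staining targets,
#'   TILED_SPARSE series with missing tiles, concatenated instances,
#'   presentation states, segmentations and parametric maps — without
#'   any external downloads. The generator retains its pre-tiling
#'   ground-truth arrays so tests can make byte-exact assertions, and
#'   the whole output is a pure function of the seed: UIDs come from a
#'   seeded factory and timestamps are fixed to a sentinel date.
#' @name fixtures
NULL

.SENTINEL_DATE <- "20240102"
.SENTINEL_TIME <- "120000"

#' Fixture generation parameters
#'
#' @slot seed Integer seed; fully determines the output.
#' @slot kind "brightfield", "fluorescence", "sparse" or
#'   "concatenated".
#' @slot base_size Base-level total matrix size (square), pixels.
#' @slot tile_size Tile size (square), pixels.
#' @slot levels Downsampling factors of the levels to emit (1 = base).
#' @slot channels Staining-target names (fluorescence; see
#'   [stainingTargetCodes()]).
#' @slot compression "none" or "jpeg".
#' @slot with_icc ICC profile variant to embed: "" (none),
#'   "identity", "swapped" or "widegamut".
#' @slot missing_tiles 0-based row-major tile indices left out of
#'   sparse instances.
#' @export
setClass("FixtureSpec", representation(
  seed = "numeric", kind = "character", base_size = "numeric",
  tile_size = "numeric", levels = "numeric", channels = "character",
  compression = "character", with_icc = "character",
  missing_tiles = "numeric"
))

#' @param seed,kind,baseSize,tileSize,levels,channels,compression,withIcc,missingTiles
#'   See slots.
#' @rdname FixtureSpec-class
#' @export
fixtureSpec <- function(seed = 1, kind = "brightfield", baseSize = 512,
                        tileSize = 256, levels = c(1, 4),
                        channels = c("DNA", "CD45"),
                        compression = "none", withIcc = "",
                        missingTiles = numeric(0)) {
  new("FixtureSpec", seed = seed, kind = kind, base_size = baseSize,
      tile_size = tileSize, levels = levels, channels = channels,
      compression = compression, with_icc = withIcc,
      missing_tiles = missingTiles)
}

.he_staining_concepts <- function() {
  list(CodedConcept("12710003", "SCT", "Hematoxylin stain"),
       CodedConcept("255801000", "SCT", "Eosin stain"))
}

.specimenSequence <- function(concepts, specimen_uid) {
  steps <- lapply(concepts, function(cc)
    dicomDataset(SpecimenPreparationStepContentItemSequence = list(
      dicomDataset(ValueType = "CODE",
                   ConceptNameCodeSequence = list(
                     codeItem(.code_using_substance())),
                   ConceptCodeSequence = list(codeItem(cc))))))
  list(dicomDataset(
    SpecimenIdentifier = "SPECIMEN-1",
    SpecimenUID = specimen_uid,
    SpecimenPreparationSequence = steps))
}

# Core instance builder: one (possibly concatenated) tiled WSI level.
.wsiInstances <- function(arr, flavor, spec, uids, study_uid, series_uid,
                          for_uid, spacing_mm, staining = list(),
                          optical_path = "1", icc = raw(0),
                          organization = "TILED_FULL",
                          missing_tiles = integer(0), concat_parts = 1L,
                          bits = 8L, container_id = "SLIDE-1",
                          specimen_uid = NULL) {
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  rows <- dim(arr)[1]; cols <- dim(arr)[2]; samples <- dim(arr)[3]
  tile <- min(spec@tile_size, rows)
  grid_rows <- ceiling(rows / tile); grid_cols <- ceiling(cols / tile)
  bg <- if (samples == 3L) 255L else 0L
  tiles <- list()
  for (tr in seq_len(grid_rows) - 1L) for (tc in seq_len(grid_cols) - 1L) {
    block <- array(bg, dim = c(tile, tile, samples))
    rr <- (tr * tile + 1):min((tr + 1) * tile, rows)
    cc <- (tc * tile + 1):min((tc + 1) * tile, cols)
    block[seq_along(rr), seq_along(cc), ] <- arr[rr, cc, , drop = FALSE]
    tiles[[length(tiles) + 1L]] <- block
  }
  keep <- setdiff(seq_along(tiles) - 1L, missing_tiles)
  positions <- cbind(row = (keep %/% grid_cols) * tile,
                     col = (keep %% grid_cols) * tile)
  tiles <- tiles[keep + 1L]
  compress <- spec@compression == "jpeg" && bits == 8L
  ts <- if (compress) UID_JPEG_BASELINE else UID_EXPLICIT_VR_LE

  photometric <- if (samples == 3L) {
    if (compress) "YBR_FULL_422" else "RGB"
  } else "MONOCHROME2"
  base <- dicomDataset(
    SOPClassUID = SOP_VL_WSI,
    StudyInstanceUID = study_uid, SeriesInstanceUID = series_uid,
    FrameOfReferenceUID = for_uid, PositionReferenceIndicator = "SLIDE_CORNER",
    Modality = "SM", Manufacturer = "dicomslide synthetic",
    ImageType = c("ORIGINAL", "PRIMARY", flavor, "NONE"),
    StudyDate = .SENTINEL_DATE, StudyTime = .SENTINEL_TIME,
    ContentDate = .SENTINEL_DATE, ContentTime = .SENTINEL_TIME,
    PatientName = "Synthetic^Specimen", PatientID = "SYN-001",
    PatientBirthDate = "19700101", PatientSex = "O",
    AccessionNumber = "1", StudyID = "1",
    ContainerIdentifier = container_id,
    Rows = tile, Columns = tile,
    SamplesPerPixel = samples, BitsAllocated = bits, BitsStored = bits,
    HighBit = bits - 1L, PixelRepresentation = 0L,
    PlanarConfiguration = 0L,
    PhotometricInterpretation = photometric,
    TotalPixelMatrixRows = rows, TotalPixelMatrixColumns = cols,
    ImagedVolumeWidth = cols * spacing_mm, ImagedVolumeHeight = rows * spacing_mm,
    ImagedVolumeDepth = 0.001,
    ImageOrientationSlide = c(1, 0, 0, 0, 1, 0),
    TotalPixelMatrixOriginSequence = list(dicomDataset(
      XOffsetInSlideCoordinateSystem = 0,
      YOffsetInSlideCoordinateSystem = 0,
      ZOffsetInSlideCoordinateSystem = 0)),
    SharedFunctionalGroupsSequence = list(dicomDataset(
      PixelMeasuresSequence = list(dicomDataset(
        PixelSpacing = c(spacing_mm, spacing_mm))))),
    BurnedInAnnotation = "NO",
    LossyImageCompression = if (compress) "01" else "00",
    SpecimenLabelInImage = if (flavor == "VOLUME") "NO" else "YES",
    FocusMethod = "AUTO", ExtendedDepthOfField = "NO",
    VolumetricProperties = "VOLUME"
  )
  path_item <- dicomDataset(OpticalPathIdentifier = optical_path,
                            OpticalPathDescription = optical_path)
  if (length(icc)) path_item <- dcmSet(path_item, "ICCProfile", icc)
  base <- dcmSet(base, "OpticalPathSequence", list(path_item))
  if (length(staining)) {
    if (is.null(specimen_uid)) specimen_uid <- uids()
    base <- dcmSet(base, "SpecimenDescriptionSequence",
                   .specimenSequence(staining, specimen_uid))
  }
  if (organization == "TILED_SPARSE") {
    base <- dcmSet(base, "DimensionOrganizationType", "TILED_SPARSE")
  } else {
    base <- dcmSet(base, "DimensionOrganizationType", "TILED_FULL")
    stopifnot(length(missing_tiles) == 0)
  }

  encodeTile <- function(block) {
    if (compress) encodeFrameJpeg(block)
    else encodeFrameBytes(block, bits)
  }

  nt <- length(tiles)
  splits <- if (concat_parts > 1L) {
    cut(seq_len(nt), breaks = concat_parts, labels = FALSE)
  } else rep(1L, nt)
  concat_uid <- if (concat_parts > 1L) uids() else NULL
  out <- list()
  for (part in seq_len(max(splits))) {
    sel <- which(splits == part)
    ds <- base
    ds <- dcmSet(ds, "SOPInstanceUID", uids())
    ds <- dcmSet(ds, "InstanceNumber", part)
    ds <- dcmSet(ds, "NumberOfFrames", length(sel))
    if (!is.null(concat_uid)) {
      ds <- dcmSet(ds, "ConcatenationUID", concat_uid)
      ds <- dcmSet(ds, "ConcatenationFrameOffsetNumber", sel[1] - 1L)
      ds <- dcmSet(ds, "InConcatenationNumber", part)
    }
    if (organization == "TILED_SPARSE") {
      pfg <- lapply(sel, function(i) dicomDataset(
        PlanePositionSlideSequence = list(dicomDataset(
          RowPositionInTotalImagePixelMatrix = positions[i, "row"] + 1L,
          ColumnPositionInTotalImagePixelMatrix = positions[i, "col"] + 1L))))
      ds <- dcmSet(ds, "PerFrameFunctionalGroupsSequence", pfg)
    }
    enc <- lapply(tiles[sel], encodeTile)
    px <- if (compress) structure(enc, class = "dcm_encapsulated")
          else do.call(c, enc)
    ds <- dcmSet(ds, "PixelData", px, vr = if (compress) "OB" else "OW")
    out[[length(out) + 1L]] <- list(dataset = ds, transferSyntax = ts)
  }
  out
}

# Deterministic "tissue-like" truth: a smooth background gradient plus
# soft elliptical blobs.
.syntheticBrightfieldTruth <- function(n, seed) {
  withSeed(seed, {
    x <- matrix(rep(seq_len(n), each = n), n) / n
    y <- matrix(rep(seq_len(n), times = n), n) / n
    r <- 230 - 40 * x; g <- 220 - 60 * y; b <- 235 - 30 * x * y
    for (i in seq_len(6)) {
      cx <- stats::runif(1); cy <- stats::runif(1)
      s <- stats::runif(1, 0.05, 0.15)
      blob <- exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
      r <- r - 90 * blob * stats::runif(1, 0.5, 1)
      g <- g - 120 * blob * stats::runif(1, 0.5, 1)
      b <- b - 40 * blob * stats::runif(1, 0.5, 1)
    }
    arr <- array(0L, dim = c(n, n, 3))
    arr[, , 1] <- pmax(pmin(round(r), 255), 0)
    arr[, , 2] <- pmax(pmin(round(g), 255), 0)
    arr[, , 3] <- pmax(pmin(round(b), 255), 0)
    storage.mode(arr) <- "integer"
    arr
  })
}

#' Generate a brightfield (H&E-like) whole-slide series
#'
#' Emits one VL Whole Slide Microscopy Image instance per pyramid
#' level (levels built by block-averaging the base truth, which is
#' also how the level-consistency property is checked), plus a LABEL
#' and an OVERVIEW image. Optionally embeds a synthetic matrix ICC
#' profile and/or compresses tiles as JPEG.
#'
#' @param spec A [FixtureSpec-class] (kind "brightfield",
#'   "sparse" or "concatenated").
#' @param uids UID generator (defaults to a factory seeded by the
#'   spec's seed).
#' @return `list(instances = list of list(dataset, transferSyntax),
#'   ground_truth = list of level arrays, study_uid, series_uid,
#'   frame_of_reference_uid, spacing_mm)`.
#' @export
makeBrightfieldSeries <- function(spec, uids = uidFactory(spec@seed)) {
  study <- uids(); series <- uids(); for_uid <- uids()
  specimen_uid <- uids()
  spacing <- 0.00025   # 0.25 um/px base spacing, 40x-class scan
  base_truth <- .syntheticBrightfieldTruth(spec@base_size, spec@seed)
  truths <- lapply(spec@levels, function(f) blockAverage(base_truth, f))
  icc <- if (nzchar(spec@with_icc)) createIccProfile(spec@with_icc) else raw(0)
  organization <- if (spec@kind == "sparse") "TILED_SPARSE" else "TILED_FULL"
  instances <- list()
  for (i in seq_along(spec@levels)) {
    f <- spec@levels[i]
    parts <- .wsiInstances(
      truths[[i]], "VOLUME", spec, uids, study, series, for_uid,
      spacing_mm = spacing * f,
      staining = .he_staining_concepts(), optical_path = "1", icc = icc,
      organization = organization,
      missing_tiles = if (f == 1) spec@missing_tiles else integer(0),
      concat_parts = if (spec@kind == "concatenated" && f == 1) 2L else 1L,
      specimen_uid = specimen_uid)
    instances <- c(instances, parts)
  }
  label <- withSeed(spec@seed + 1, {
    arr <- array(as.integer(sample.int(256, 64 * 64 * 3, TRUE) - 1),
                 dim = c(64, 64, 3))
  })
  overview <- blockAverage(base_truth, max(4, spec@base_size / 64))
  lab_spec <- spec; lab_spec@tile_size <- 64
  instances <- c(instances, .wsiInstances(
    label, "LABEL", lab_spec, uids, study, uids(), for_uid,
    spacing_mm = 0.01, staining = .he_staining_concepts(),
    specimen_uid = specimen_uid))
  ov_spec <- spec; ov_spec@tile_size <- max(dim(overview)[1], 1)
  instances <- c(instances, .wsiInstances(
    overview, "OVERVIEW", ov_spec, uids, study, uids(), for_uid,
    spacing_mm = spacing * spec@base_size / dim(overview)[1],
    staining = .he_staining_concepts(), specimen_uid = specimen_uid))
  list(instances = instances, ground_truth = truths, study_uid = study,
       series_uid = series, frame_of_reference_uid = for_uid,
       spacing_mm = spacing)
}

# Disjoint Gaussian blobs per channel; masks mark blob support.
.syntheticChannelTruth <- function(n, seed, channel_index, n_channels) {
  withSeed(seed * 1000 + channel_index, {
    x <- matrix(rep(seq_len(n), each = n), n) / n
    y <- matrix(rep(seq_len(n), times = n), n) / n
    # centers on a channel-specific grid column so channel supports
    # stay disjoint
    cx <- (channel_index - 0.5) / n_channels
    cy <- stats::runif(1, 0.25, 0.75)
    s <- 0.4 / n_channels
    blob <- exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
    img <- round(60000 * blob + 500 * stats::runif(n * n))
    img <- pmin(img, 65535)
    truth <- matrix(as.integer(img), n)
    list(truth = truth, mask = blob > 0.1)
  })
}

#' Generate a multichannel fluorescence series set
#'
#' One 16-bit monochrome series per channel (all sharing study and
#' frame of reference), each carrying its staining target as a coded
#' specimen-preparation substance and its optical path identifier.
#' Channel blobs are spatially disjoint by construction, which is
#' what the blending tests rely on.
#'
#' @param spec A [FixtureSpec-class] (kind "fluorescence"); channels
#'   are staining-target names from [stainingTargetCodes()].
#' @param uids UID generator.
#' @return `list(instances, ground_truth = per-channel list of level
#'   arrays, masks = per-channel logical matrices, study_uid,
#'   frame_of_reference_uid, channel_series = named uid vector)`.
#' @export
makeFluorescenceSeries <- function(spec, uids = uidFactory(spec@seed)) {
  stopifnot(length(spec@channels) >= 1)
  study <- uids(); for_uid <- uids()
  specimen_uid <- uids()
  spacing <- 0.000325
  instances <- list(); truths <- list(); masks <- list()
  series_uids <- character(0)
  for (ci in seq_along(spec@channels)) {
    ch <- spec@channels[ci]
    series <- uids()
    series_uids[ch] <- series
    tm <- .syntheticChannelTruth(spec@base_size, spec@seed, ci,
                                 length(spec@channels))
    lv_truths <- lapply(spec@levels, function(f) blockAverage(tm$truth, f))
    for (i in seq_along(spec@levels)) {
      f <- spec@levels[i]
      parts <- .wsiInstances(
        lv_truths[[i]], "VOLUME", spec, uids, study, series, for_uid,
        spacing_mm = spacing * f,
        staining = list(.stainingConcept(ch)),
        optical_path = ch, bits = 16L, specimen_uid = specimen_uid,
        organization = if (spec@kind == "sparse") "TILED_SPARSE"
                       else "TILED_FULL",
        missing_tiles = if (spec@kind == "sparse" && f == 1)
          spec@missing_tiles else integer(0))
      instances <- c(instances, parts)
    }
    truths[[ch]] <- lv_truths
    masks[[ch]] <- tm$mask
  }
  list(instances = instances, ground_truth = truths, masks = masks,
       study_uid = study, frame_of_reference_uid = for_uid,
       channel_series = series_uids, spacing_mm = spacing)
}

#' Generate analysis-result objects for a source series
#'
#' From a polygon specification on the source image's base level,
#' derives the four standard analysis-result objects: a Comprehensive
#' 3D SR measurement report (one ROI per polygon, with computed area
#' and perimeter), a Microscopy Bulk Simple Annotations dataset, a
#' binary and a fractional Segmentation, and a Parametric Map with a
#' linear real-world value mapping onto `realRange`.
#'
#' @param source Source image `DicomDataset` (base level).
#' @param polygons List of n x 2 (column, row) pixel-vertex matrices.
#' @param uids UID generator.
#' @param realRange Real-world range of the parametric map.
#' @return `list(sr, bulk, segmentation_binary,
#'   segmentation_fractional, parametric_map, report, mask)`.
#' @export
makeAnalysisObjects <- function(source, polygons, uids = uidFactory(99),
                                realRange = c(-1, 1)) {
  md <- .parseTiledImageMetadata(source)
  map <- buildPixelToSlide(md)
  rois <- lapply(seq_along(polygons), function(i) {
    g <- roiFromPixels("POLYGON", polygons[[i]], map,
                       md@frame_of_reference_uid)
    roiAnnotation(trackingId = sprintf("ROI-%d", i), trackingUid = uids(),
                  graphic = g,
                  finding = CodedConcept("84640000", "SCT", "Nucleus"),
                  measurements = measureRoi(g))
  })
  report <- measurementReport(
    observer = "Synthetic^Algorithm", observerType = "person",
    rois = rois, study = md@study_uid,
    referencedImages = list(list(study = md@study_uid,
                                 series = md@series_uid,
                                 instance = md@sop_instance_uid,
                                 sop_class = SOP_VL_WSI)),
    frameOfReference = md@frame_of_reference_uid)
  sr <- encodeMeasurementReport(report, uids)
  mask <- rasterizePolygons(polygons, md@total_rows, md@total_cols)
  areas <- vapply(polygons, function(p)
    .shoelace_area(p), 0) * md@pixel_spacing_row_mm * md@pixel_spacing_col_mm
  group <- list(label = CodedConcept("84640000", "SCT", "Nucleus"),
                graphic_type = "POLYGON", polygons = polygons,
                measurements = list(list(
                  name = .code_area(), unit = .ucum_mm2(), values = areas)))
  bulk <- buildBulkAnnotations(list(group), source, uids)
  seg_bin <- buildSegmentationDataset(mask, source, "BINARY", uids)
  seg_frac <- buildSegmentationDataset(mask * 1, source, "FRACTIONAL", uids)
  ramp <- matrix(rep(seq(realRange[1], realRange[2],
                         length.out = md@total_cols),
                     each = md@total_rows), md@total_rows)
  pm <- buildParametricMapDataset(ramp, source, realRange = realRange,
                                  uids = uids)
  list(sr = sr, bulk = bulk, segmentation_binary = seg_bin,
       segmentation_fractional = seg_frac, parametric_map = pm,
       report = report, mask = mask)
}

#' Populate a local store with a complete fixture study set
#'
#' Builds a brightfield slide, a multiplexed fluorescence slide (nine
#' default staining targets), the three default blending presentation
#' states, and analysis objects for the brightfield slide, and stores
#' everything into a [LocalStore-class] at `path`.
#'
#' @param path Store directory.
#' @param seed Integer seed.
#' @param baseSize,tileSize Geometry of the generated slides.
#' @return The populated [LocalStore-class] (invisibly, with the
#'   generation artifacts attached as attribute "fixtures").
#' @export
writeFixtureStore <- function(path, seed = 1, baseSize = 512,
                              tileSize = 256) {
  store <- localStore(path)
  uids <- uidFactory(seed)
  bf <- makeBrightfieldSeries(fixtureSpec(
    seed = seed, kind = "brightfield", baseSize = baseSize,
    tileSize = tileSize, levels = c(1, 4), withIcc = "identity"), uids)
  fl <- makeFluorescenceSeries(fixtureSpec(
    seed = seed + 1, kind = "fluorescence", baseSize = baseSize,
    tileSize = tileSize, levels = 1,
    channels = stainingTargetCodes()$name), uids)
  storeInstances(store, c(bf$instances, fl$instances))
  metas <- lapply(fl$instances, function(x) {
    ds <- dcmSet(x$dataset, "TransferSyntaxUID", x$transferSyntax)
    parseImageMetadata(ds)
  })
  slide <- groupSlides(metas)[[1L]]
  states <- defaultStainingGroups(slide)
  state_ds <- lapply(states, buildPresentationState, slide = slide,
                     uids = uids)
  storeInstances(store, state_ds)
  n <- baseSize
  polys <- list(
    cbind(c(10, 40, 40, 10), c(10, 10, 40, 40)),
    cbind(c(60, 90, 75), c(60, 60, 90)))
  analysis <- makeAnalysisObjects(bf$instances[[1L]]$dataset, polys, uids)
  storeInstances(store, list(analysis$sr, analysis$bulk,
                             analysis$segmentation_binary,
                             analysis$segmentation_fractional,
                             analysis$parametric_map))
  attr(store, "fixtures") <- list(brightfield = bf, fluorescence = fl,
                                  states = states, analysis = analysis)
  invisible(store)
}
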