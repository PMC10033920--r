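#' @title Bulk annotations, rasterization and contour conversion
#'
#' @description Computational analyses produce very large numbers of
#'   ROIs (e.g. per-nucleus contours) that are impractical as one SR
#'   content item each. DICOM Microscopy Bulk Simple Annotations store
#'   the coordinates of a whole annotation group in flat arrays with
#'   parallel per-ROI measurement vectors; Segmentations store the
#'   rasterized masks. This module parses and builds both, and
#'   converts tabular contour data (CSV) into the pair of standard
#'   objects, copying descriptive metadata from the source images so
#'   the derived objects remain linked to their slide.
#' @name annotations-convert
NULL

# Attributes copied from source images into derived objects.
.descriptive_keywords <- c(
  "PatientName", "PatientID", "PatientBirthDate", "PatientSex",
  "StudyInstanceUID", "StudyID", "StudyDate", "StudyTime",
  "AccessionNumber", "FrameOfReferenceUID", "ContainerIdentifier",
  "SpecimenDescriptionSequence")

.copyDescriptiveMetadata <- function(source, target) {
  for (kw in .descriptive_keywords) {
    if (dcmHas(source, kw))
      target[[kw]] <- source[[kw]]
  }
  target
}

.sourceImageRefs <- function(source) {
  list(dicomDataset(
    ReferencedSOPClassUID = dcmValue(source, "SOPClassUID", SOP_VL_WSI),
    ReferencedSOPInstanceUID = dcmValue(source, "SOPInstanceUID", "")))
}

# ---- rasterization ----------------------------------------------------

# Even-odd point-in-polygon; points whose center lies exactly on a
# boundary edge count as inside.
.pointInPolygon <- function(px, py, xs, ys, eps = 1e-9) {
  n <- length(xs)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint[crosses])
    }
    # on-segment test
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - xi) * dx + (py - yi) * dy) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
      on_edge <- on_edge | d2 < eps
    }
    j <- i
  }
  inside | on_edge
}

#' Rasterize polygons onto a pixel grid
#'
#' A pixel is foreground iff its center lies inside any polygon under
#' the even-odd rule; centers exactly on a boundary count as inside.
#' Pixel centers are at integer (column, row) coordinates, matching
#' the geometry module's pixel-center convention.
#'
#' @param polygons List of n x 2 matrices of (column, row) vertices in
#'   pixel coordinates (open or closed).
#' @param rows,cols Grid size.
#' @return Logical matrix `rows x cols`.
#' @export
rasterizePolygons <- function(polygons, rows, cols) {
  mask <- matrix(FALSE, rows, cols)
  for (poly in polygons) {
    poly <- .as_points(poly, 2L)
    if (all(poly[1, ] == poly[nrow(poly), ]) && nrow(poly) > 1)
      poly <- poly[-nrow(poly), , drop = FALSE]
    c0 <- max(0L, floor(min(poly[, 1]))); c1 <- min(cols - 1L, ceiling(max(poly[, 1])))
    r0 <- max(0L, floor(min(poly[, 2]))); r1 <- min(rows - 1L, ceiling(max(poly[, 2])))
    if (c1 < c0 || r1 < r0) next
    cc <- rep(c0:c1, each = r1 - r0 + 1L)
    rr <- rep(r0:r1, times = c1 - c0 + 1L)
    hit <- .pointInPolygon(cc, rr, poly[, 1], poly[, 2])
    mask[cbind(rr + 1L, cc + 1L)] <- mask[cbind(rr + 1L, cc + 1L)] | hit
  }
  mask
}

# ---- segmentation / parametric map builders ---------------------------

.tileFrames <- function(total, tile_rows, tile_cols, pad = 0) {
  rows <- nrow(total); cols <- ncol(total)
  grid_rows <- ceiling(rows / tile_rows); grid_cols <- ceiling(cols / tile_cols)
  frames <- list()
  for (tr in seq_len(grid_rows) - 1L) {
    for (tc in seq_len(grid_cols) - 1L) {
      tile <- matrix(pad, tile_rows, tile_cols)
      rr <- (tr * tile_rows + 1):min((tr + 1) * tile_rows, rows)
      cc <- (tc * tile_cols + 1):min((tc + 1) * tile_cols, cols)
      tile[seq_along(rr), seq_along(cc)] <- total[rr, cc]
      frames[[length(frames) + 1L]] <- tile
    }
  }
  frames
}

#' Build a DICOM Segmentation dataset from a mask
#'
#' Binary masks are packed one bit per pixel (each frame padded to a
#' byte boundary); fractional masks are stored as 8-bit fractions of
#' `MaximumFractionalValue` 255 with segmentation fractional type
#' PROBABILITY. The mask is tiled to match the source image tiling,
#' TILED_FULL, and descriptive patient/study/specimen metadata plus
#' source-image references are copied from the source dataset.
#'
#' @param mask Numeric or logical matrix in base-level pixel grid
#'   (binary: logical / 0-1; fractional: values in [0, 1]).
#' @param source Source image `DicomDataset`.
#' @param type "BINARY" or "FRACTIONAL".
#' @param uids UID generator.
#' @param label Segment label.
#' @return A `DicomDataset`.
#' @export
buildSegmentationDataset <- function(mask, source, type = c("BINARY",
                                                            "FRACTIONAL"),
                                     uids = uidFactory(), label = "Nuclei") {
  type <- match.arg(type)
  md <- .parseTiledImageMetadata(source)
  tile_rows <- md@tile_rows; tile_cols <- md@tile_cols
  frames <- .tileFrames(mask, tile_rows, tile_cols)
  if (type == "BINARY") {
    px <- do.call(c, lapply(frames, function(tile) {
      v <- as.logical(t(tile))             # row-major within the frame
      packBits(c(v, rep(FALSE, (8 - length(v) %% 8) %% 8)), type = "raw")
    }))
    bits <- 1L
  } else {
    px <- do.call(c, lapply(frames, function(tile)
      encodeFrameBytes(matrix(as.integer(round(tile * 255)),
                              nrow(tile), ncol(tile)), 8L)))
    bits <- 8L
  }
  ds <- dicomDataset(
    SOPClassUID = SOP_SEGMENTATION,
    SOPInstanceUID = uids(),
    SeriesInstanceUID = uids(),
    Modality = "SEG",
    ImageType = c("DERIVED", "PRIMARY", "VOLUME", "NONE"),
    InstanceNumber = 1L,
    Rows = tile_rows, Columns = tile_cols,
    TotalPixelMatrixRows = nrow(mask), TotalPixelMatrixColumns = ncol(mask),
    NumberOfFrames = length(frames),
    SamplesPerPixel = 1L, BitsAllocated = bits, BitsStored = bits,
    HighBit = max(bits - 1L, 0L), PixelRepresentation = 0L,
    PhotometricInterpretation = "MONOCHROME2",
    DimensionOrganizationType = "TILED_FULL",
    SegmentationType = type,
    SegmentSequence = list(dicomDataset(
      SegmentNumber = 1L, SegmentLabel = label,
      SegmentAlgorithmType = "AUTOMATIC",
      SegmentAlgorithmName = "dicomslide-contours")),
    SourceImageSequence = .sourceImageRefs(source),
    PixelData = px
  )
  if (type == "FRACTIONAL") {
    ds <- dcmSet(ds, "SegmentationFractionalType", "PROBABILITY")
    ds <- dcmSet(ds, "MaximumFractionalValue", 255L)
  }
  for (kw in c("SharedFunctionalGroupsSequence",
               "TotalPixelMatrixOriginSequence", "ImageOrientationSlide"))
    if (dcmHas(source, kw)) ds[[kw]] <- source[[kw]]
  .copyDescriptiveMetadata(source, ds)
}

#' Build a DICOM Parametric Map dataset
#'
#' Stored values are 16-bit unsigned integers; a linear real-world
#' value mapping (slope, intercept) relates them to the quantity the
#' map encodes (default real range [-1, 1] over the full stored
#' range).
#'
#' @param values Numeric matrix of real-world values.
#' @param source Source image `DicomDataset`.
#' @param realRange Length-2 real-world range mapped onto stored
#'   [0, 65535].
#' @param unit UCUM [CodedConcept-class] of the real-world quantity.
#' @param uids UID generator.
#' @return A `DicomDataset`.
#' @export
buildParametricMapDataset <- function(values, source,
                                      realRange = c(-1, 1),
                                      unit = CodedConcept("1", "UCUM",
                                                          "no units"),
                                      uids = uidFactory()) {
  md <- .parseTiledImageMetadata(source)
  slope <- (realRange[2] - realRange[1]) / 65535
  intercept <- realRange[1]
  stored <- matrix(as.integer(round((values - intercept) / slope)),
                   nrow(values), ncol(values))
  if (any(stored < 0 | stored > 65535))
    dcmStop("value_range", "values outside the declared real range")
  frames <- .tileFrames(stored, md@tile_rows, md@tile_cols)
  px <- do.call(c, lapply(frames, function(tile) encodeFrameBytes(tile, 16L)))
  ds <- dicomDataset(
    SOPClassUID = SOP_PARAMETRIC_MAP,
    SOPInstanceUID = uids(),
    SeriesInstanceUID = uids(),
    Modality = "OT",
    ImageType = c("DERIVED", "PRIMARY", "VOLUME", "NONE"),
    InstanceNumber = 1L,
    Rows = md@tile_rows, Columns = md@tile_cols,
    TotalPixelMatrixRows = nrow(values),
    TotalPixelMatrixColumns = ncol(values),
    NumberOfFrames = length(frames),
    SamplesPerPixel = 1L, BitsAllocated = 16L, BitsStored = 16L,
    HighBit = 15L, PixelRepresentation = 0L,
    PhotometricInterpretation = "MONOCHROME2",
    DimensionOrganizationType = "TILED_FULL",
    RealWorldValueMappingSequence = list(dicomDataset(
      RealWorldValueFirstValueMapped = 0L,
      RealWorldValueLastValueMapped = 65535L,
      RealWorldValueSlope = slope,
      RealWorldValueIntercept = intercept,
      LUTLabel = "REAL",
      MeasurementUnitsCodeSequence = list(codeItem(unit)))),
    SourceImageSequence = .sourceImageRefs(source),
    PixelData = px
  )
  for (kw in c("SharedFunctionalGroupsSequence",
               "TotalPixelMatrixOriginSequence", "ImageOrientationSlide"))
    if (dcmHas(source, kw)) ds[[kw]] <- source[[kw]]
  .copyDescriptiveMetadata(source, ds)
}

# ---- bulk annotations -------------------------------------------------

#' Build a Microscopy Bulk Simple Annotations dataset
#'
#' @param groups List of groups, each `list(label = CodedConcept,
#'   graphic_type = "POINT"|"POLYGON"|"POLYLINE", polygons = list of
#'   n x 2 (column, row) pixel matrices, measurements = list of
#'   list(name = CodedConcept, unit = UCUM CodedConcept, values =
#'   numeric per-ROI vector))`.
#' @param source Source image `DicomDataset`.
#' @param uids UID generator.
#' @return A `DicomDataset`.
#' @export
buildBulkAnnotations <- function(groups, source, uids = uidFactory()) {
  items <- lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    polys <- lapply(g$polygons, .as_points, ncols = 2L)
    counts <- vapply(polys, nrow, 0L)
    coords <- do.call(rbind, polys)
    idx <- cumsum(c(1, 2 * counts[-length(counts)]))  # 1-based value index
    item <- dicomDataset(
      AnnotationGroupNumber = gi,
      AnnotationGroupUID = uids(),
      AnnotationGroupLabel = g$label@meaning,
      AnnotationGroupGenerationType = "AUTOMATIC",
      AnnotationPropertyTypeCodeSequence = list(codeItem(g$label)),
      GraphicType = g$graphic_type,
      NumberOfAnnotations = length(polys),
      AnnotationAppliesToAllOpticalPaths = "YES",
      PointCoordinatesData = writeBin(as.numeric(t(coords)), raw(),
                                      size = 4L, endian = "little")
    )
    if (g$graphic_type != "POINT")
      item <- dcmSet(item, "LongPrimitivePointIndexList",
                     packIntLE(idx, 4L))
    if (length(g$measurements %||% list())) {
      meas_items <- lapply(g$measurements, function(m)
        dicomDataset(
          ConceptNameCodeSequence = list(codeItem(m$name)),
          MeasurementUnitsCodeSequence = list(codeItem(m$unit)),
          MeasurementValuesSequence = list(dicomDataset(
            FloatingPointValues = writeBin(as.numeric(m$values), raw(),
                                           size = 4L, endian = "little")))))
      item <- dcmSet(item, "MeasurementsSequence", meas_items)
    }
    item
  })
  ds <- dicomDataset(
    SOPClassUID = SOP_BULK_ANNOTATIONS,
    SOPInstanceUID = uids(),
    SeriesInstanceUID = uids(),
    Modality = "ANN",
    InstanceNumber = 1L,
    AnnotationCoordinateType = "2D",
    AnnotationGroupSequence = items,
    SourceImageSequence = .sourceImageRefs(source)
  )
  .copyDescriptiveMetadata(source, ds)
}

#' Parse a Microscopy Bulk Simple Annotations dataset
#'
#' Coordinates are exposed both raw (pixel space of the referenced
#' base level) and, when an affine map is supplied, as 3D slide-space
#' millimeters. Groups whose coordinate data are inconsistent with
#' the declared graphic type or counts raise a group error.
#'
#' @param ds A `DicomDataset`.
#' @param map Optional [AffineMap-class] for mm conversion.
#' @return List of groups: `list(label, graphic_type, count,
#'   points_px = list of n x 2 matrices, points_mm = list of n x 3 or
#'   NULL, measurements = list of list(name, unit, values))`.
#' @export
parseBulkAnnotations <- function(ds, map = NULL) {
  if (!identical(dcmValue(ds, "SOPClassUID", ""), SOP_BULK_ANNOTATIONS))
    dcmStop("wrong_sop_class",
            "dataset is not a Microscopy Bulk Simple Annotations object")
  lapply(dcmValue(ds, "AnnotationGroupSequence", list()), function(item) {
    n <- as.integer(dcmValue(item, "NumberOfAnnotations", 0))
    gt <- dcmValue(item, "GraphicType", "")
    vals <- readBin(dcmValue(item, "PointCoordinatesData", raw(0)), "double",
                    n = length(dcmValue(item, "PointCoordinatesData",
                                        raw(0))) %/% 4L,
                    size = 4L, endian = "little")
    if (gt == "POINT") {
      if (length(vals) != 2 * n)
        dcmStop("group", "POINT group: %d coordinate values for %d points",
                length(vals), n)
      polys <- lapply(seq_len(n), function(i)
        matrix(vals[(2 * i - 1):(2 * i)], 1, 2))
    } else {
      idx <- unpackIntLE(dcmValue(item, "LongPrimitivePointIndexList",
                                  raw(0)), 4L)
      if (length(idx) != n)
        dcmStop("group", "%s group: %d indices for %d annotations", gt,
                length(idx), n)
      bounds <- c(idx, length(vals) + 1)
      if (any(diff(bounds) <= 0) || any(bounds[-length(bounds)] > length(vals)))
        dcmStop("group",
                "%s group: declared item extent exceeds coordinate data", gt)
      min_pts <- if (gt == "POLYGON") 3L else 2L
      polys <- lapply(seq_len(n), function(i) {
        seg <- vals[bounds[i]:(bounds[i + 1] - 1)]
        if (length(seg) %% 2 != 0)
          dcmStop("group", "%s group: odd coordinate count in item %d", gt, i)
        if (length(seg) < 2L * min_pts)
          dcmStop("group",
                  "%s group: item %d declares fewer than %d points", gt, i,
                  min_pts)
        matrix(seg, ncol = 2, byrow = TRUE)
      })
    }
    meas <- lapply(dcmValue(item, "MeasurementsSequence", list()),
                   function(m) {
      mv <- dcmValue(m, "MeasurementValuesSequence", list())
      values <- if (length(mv)) {
        fp <- dcmValue(mv[[1L]], "FloatingPointValues", raw(0))
        readBin(fp, "double", n = length(fp) %/% 4L, size = 4L,
                endian = "little")
      } else numeric(0)
      if (length(values) != n)
        dcmStop("group", "measurement array length %d != ROI count %d",
                length(values), n)
      nm <- dcmValue(m, "ConceptNameCodeSequence", list())
      un <- dcmValue(m, "MeasurementUnitsCodeSequence", list())
      list(name = if (length(nm)) codeFromItem(nm[[1L]]) else NULL,
           unit = if (length(un)) codeFromItem(un[[1L]]) else NULL,
           values = values)
    })
    label_seq <- dcmValue(item, "AnnotationPropertyTypeCodeSequence", list())
    list(
      label = if (length(label_seq)) codeFromItem(label_seq[[1L]]) else NULL,
      graphic_type = gt,
      count = n,
      points_px = polys,
      points_mm = if (!is.null(map)) lapply(polys, pixelToSlide, map = map)
                  else NULL,
      measurements = meas)
  })
}

# ---- contour table conversion ----------------------------------------

.parse_vertices <- function(s) {
  pairs <- strsplit(trimws(strsplit(s, ";", fixed = TRUE)[[1L]]), "[ ,]+")
  m <- t(vapply(pairs, function(p) suppressWarnings(as.numeric(p[1:2])),
                c(0, 0)))
  if (anyNA(m)) stop("unparseable vertex list")
  m
}

#' Convert a contour table (CSV) to standard DICOM objects
#'
#' Reads per-object polygon contours in base-level pixel coordinates
#' plus optional per-object measurement columns, and emits (i) a
#' Microscopy Bulk Simple Annotations dataset carrying the polygon
#' coordinates and measurement vectors and (ii) a binary Segmentation
#' dataset rasterizing the union of the polygons, tiled to match the
#' source image. Both reference the source image and copy its
#' patient/study/specimen metadata.
#'
#' CSV dialect: columns `object_id`, `vertices`
#' (semicolon-separated "column row" pairs, e.g. `"10 10;20 10;20
#' 20"`), plus any numeric measurement columns (UCUM unit taken as
#' dimensionless unless the column is named `area_mm2` or
#' `length_mm`).
#'
#' @param csv Path to the CSV file, or a data.frame.
#' @param source Source image `DicomDataset`.
#' @param uids UID generator.
#' @param label Coded label of the annotation group.
#' @return `list(bulk, segmentation, errors)` — `errors` is a
#'   character vector of row-level problems (empty when clean).
#' @export
convertContourTable <- function(csv, source, uids = uidFactory(),
                                label = CodedConcept("84640000", "SCT",
                                                     "Nucleus")) {
  df <- if (is.data.frame(csv)) csv else utils::read.csv(csv,
                                                         stringsAsFactors = FALSE)
  if (!nrow(df)) dcmStop("empty_input", "contour table contains no rows")
  if (!all(c("object_id", "vertices") %in% names(df)))
    dcmStop("empty_input",
            "contour table must have object_id and vertices columns")
  md <- .parseTiledImageMetadata(source)
  polys <- list(); keep <- integer(0); errors <- character(0)
  for (i in seq_len(nrow(df))) {
    v <- tryCatch(.parse_vertices(df$vertices[i]), error = function(e) NULL)
    if (is.null(v) || nrow(v) < 3) {
      errors <- c(errors, sprintf("row %d (object %s): unparseable vertices",
                                  i, df$object_id[i]))
      next
    }
    clipped <- v
    clipped[, 1] <- pmin(pmax(clipped[, 1], 0), md@total_cols - 1)
    clipped[, 2] <- pmin(pmax(clipped[, 2], 0), md@total_rows - 1)
    if (!identical(clipped, v))
      dcmWarn("clipped_vertices",
              "row %d: vertices outside the total pixel matrix were clipped", i)
    polys[[length(polys) + 1L]] <- clipped
    keep <- c(keep, i)
  }
  if (!length(polys))
    dcmStop("empty_input", "no convertible contours in table")
  meas_cols <- setdiff(names(df)[vapply(df, is.numeric, TRUE)], "object_id")
  unit_for <- function(col) {
    if (grepl("mm2$", col)) .ucum_mm2()
    else if (grepl("mm$", col)) .ucum_mm()
    else CodedConcept("1", "UCUM", "no units")
  }
  measurements <- lapply(meas_cols, function(col)
    list(name = CodedConcept(col, "99DSL", col), unit = unit_for(col),
         values = as.numeric(df[[col]][keep])))
  group <- list(label = label, graphic_type = "POLYGON", polygons = polys,
                measurements = measurements)
  mask <- rasterizePolygons(polys, md@total_rows, md@total_cols)
  list(bulk = buildBulkAnnotations(list(group), source, uids),
       segmentation = buildSegmentationDataset(mask, source, "BINARY", uids),
       errors = errors)
}

# ---- GeoJSON interoperability ----------------------------------------

#' Export ROI geometry as GeoJSON (pixel space)
#'
#' Coordinates are written in base-level pixel space, applying the
#' inverse affine map, which is the convention annotation GUIs use.
#' [roisFromGeoJson()] inverts the conversion.
#'
#' @param rois List of [RoiAnnotation-class] or [RoiGraphic-class].
#' @param map The slide's base-level [AffineMap-class].
#' @return GeoJSON text (FeatureCollection).
#' @export
roisToGeoJson <- function(rois, map) {
  features <- lapply(rois, function(roi) {
    g <- if (is(roi, "RoiAnnotation")) roi@graphic else roi
    px <- slideToPixel(map, g@points)
    coords <- lapply(seq_len(nrow(px)), function(i) c(px[i, 1], px[i, 2]))
    geometry <- switch(g@graphic_type,
      POINT = list(type = "Point", coordinates = coords[[1L]]),
      POLYLINE = list(type = "LineString", coordinates = coords),
      POLYGON = list(type = "Polygon", coordinates = list(coords)),
      dcmStop("geometry", "%s has no GeoJSON equivalent", g@graphic_type))
    props <- if (is(roi, "RoiAnnotation"))
      list(tracking_identifier = roi@tracking_identifier,
           tracking_uid = roi@tracking_uid)
    else list()
    list(type = "Feature", geometry = geometry,
         properties = props)
  })
  as.character(jsonlite::toJSON(
    list(type = "FeatureCollection", features = features),
    auto_unbox = TRUE, digits = NA))
}

#' @param json GeoJSON text.
#' @param frameOfReference Frame of reference UID for the created
#'   graphics.
#' @rdname roisToGeoJson
#' @return `roisFromGeoJson`: list of [RoiGraphic-class].
#' @export
roisFromGeoJson <- function(json, map, frameOfReference) {
  fc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  lapply(fc$features, function(f) {
    geom <- f$geometry
    to_mat <- function(coords)
      t(vapply(coords, function(p) as.numeric(unlist(p[1:2])), c(0, 0)))
    switch(geom$type,
      Point = roiFromPixels("POINT", matrix(as.numeric(unlist(
        geom$coordinates[1:2])), 1, 2), map, frameOfReference),
      LineString = roiFromPixels("POLYLINE", to_mat(geom$coordinates), map,
                                 frameOfReference),
      Polygon = roiFromPixels("POLYGON", to_mat(geom$coordinates[[1L]]), map,
                              frameOfReference),
      dcmStop("geometry", "unsupported GeoJSON geometry %s", geom$type))
  })
}
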