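#' @title ROI annotations and structured-report measurement documents
#'
#' @description Regions of interest drawn on a slide are tracked as
#'   SCOORD3D geometry — 3D slide coordinates in millimeters, which
#'   makes them valid for every image of the slide regardless of
#'   channel or resolution level — and stored together with coded
#'   qualitative evaluations and UCUM-coded measurements in DICOM
#'   Comprehensive 3D SR documents structured as a measurement report
#'   (one planar-ROI measurement group per region).
#' @name annotations
NULL

.valid_graphic_types <- c("POINT", "POLYLINE", "POLYGON", "ELLIPSE",
                          "ELLIPSOID")

#' ROI graphic in slide coordinates
#'
#' @slot graphic_type POINT, POLYLINE, POLYGON, ELLIPSE or ELLIPSOID.
#' @slot points Numeric matrix n x 3 of (x, y, z) mm. POINT: 1 point;
#'   POLYLINE: >= 2; POLYGON: closed (first equals last, >= 4 stored
#'   points); ELLIPSE: 4 points (major-axis endpoints then minor-axis
#'   endpoints); ELLIPSOID: 6 points.
#' @slot frame_of_reference_uid The slide's frame of reference.
#' @export
setClass("RoiGraphic", representation(
  graphic_type = "character", points = "matrix",
  frame_of_reference_uid = "character"
))

setValidity("RoiGraphic", function(object) {
  gt <- object@graphic_type
  n <- nrow(object@points)
  if (!gt %in% .valid_graphic_types)
    return(sprintf("unknown graphic type %s", gt))
  if (ncol(object@points) != 3) return("points must be n x 3 (x, y, z)")
  ok <- switch(gt,
               POINT = n == 1,
               POLYLINE = n >= 2,
               POLYGON = n >= 4 &&
                 all(object@points[1, ] == object@points[n, ]),
               ELLIPSE = n == 4,
               ELLIPSOID = n == 6)
  if (!ok) return(sprintf("invalid point count (%d) for %s", n, gt))
  TRUE
})

#' @param graphicType,points,frameOfReference See slots.
#' @rdname RoiGraphic-class
#' @export
roiGraphic <- function(graphicType, points, frameOfReference) {
  new("RoiGraphic", graphic_type = graphicType,
      points = .as_points(points, 3L),
      frame_of_reference_uid = frameOfReference)
}

#' Qualitative evaluation (coded name-value pair)
#' @slot name,value [CodedConcept-class]s.
#' @export
setClass("Evaluation", representation(name = "CodedConcept",
                                      value = "CodedConcept"))

#' @param name,value See slots.
#' @rdname Evaluation-class
#' @export
evaluation <- function(name, value) new("Evaluation", name = name,
                                        value = value)

#' Numeric measurement with UCUM unit
#' @slot name [CodedConcept-class] measurement concept.
#' @slot value Numeric value.
#' @slot unit [CodedConcept-class] from the UCUM scheme.
#' @export
setClass("Measurement", representation(
  name = "CodedConcept", value = "numeric", unit = "CodedConcept"
))

setValidity("Measurement", function(object) {
  if (object@unit@scheme != "UCUM")
    return("measurement units must come from the UCUM coding scheme")
  TRUE
})

#' @param name,value,unit See slots.
#' @rdname Measurement-class
#' @export
measurement <- function(name, value, unit) {
  new("Measurement", name = name, value = as.numeric(value), unit = unit)
}

.ucum_mm <- function() CodedConcept("mm", "UCUM", "millimeter")
.ucum_mm2 <- function() CodedConcept("mm2", "UCUM", "square millimeter")
.code_area <- function() CodedConcept("42798000", "SCT", "Area")
.code_perimeter <- function() CodedConcept("131191004", "SCT", "Perimeter")
.code_length <- function() CodedConcept("410668003", "SCT", "Length")
.code_circumference <- function() CodedConcept("74551000", "SCT",
                                               "Circumference")

#' One annotated region of interest
#'
#' @slot tracking_identifier Human-readable tracking label.
#' @slot tracking_uid Unique tracking identifier (unique per report).
#' @slot finding Optional [CodedConcept-class] (`NULL` if absent).
#' @slot graphic [RoiGraphic-class].
#' @slot evaluations List of [Evaluation-class].
#' @slot measurements List of [Measurement-class].
#' @export
setClass("RoiAnnotation", representation(
  tracking_identifier = "character", tracking_uid = "character",
  finding = "ANY", graphic = "RoiGraphic",
  evaluations = "list", measurements = "list"
))

#' @param trackingId,trackingUid,graphic,finding,evaluations,measurements
#'   See slots.
#' @rdname RoiAnnotation-class
#' @export
roiAnnotation <- function(trackingId, trackingUid, graphic, finding = NULL,
                          evaluations = list(), measurements = list()) {
  new("RoiAnnotation", tracking_identifier = trackingId,
      tracking_uid = trackingUid, finding = finding, graphic = graphic,
      evaluations = evaluations, measurements = measurements)
}

#' A measurement report (collection of annotated ROIs)
#'
#' @slot observer_name Person name or device identifier.
#' @slot observer_type "person" or "device".
#' @slot study_uid Study the report belongs to.
#' @slot referenced_images List of `list(study, series, instance,
#'   sop_class)` source-image references.
#' @slot rois List of [RoiAnnotation-class]; tracking UIDs unique and
#'   all frames of reference equal to the referenced images'.
#' @slot frame_of_reference_uid Common frame of reference.
#' @export
setClass("MeasurementReport", representation(
  observer_name = "character", observer_type = "character",
  study_uid = "character", referenced_images = "list", rois = "list",
  frame_of_reference_uid = "character"
))

setValidity("MeasurementReport", function(object) {
  uids <- vapply(object@rois, function(r) r@tracking_uid, "")
  if (anyDuplicated(uids)) return("tracking UIDs must be unique")
  fors <- vapply(object@rois, function(r) r@graphic@frame_of_reference_uid, "")
  if (length(fors) && !all(fors == object@frame_of_reference_uid))
    return("all ROI frames of reference must match the report's")
  TRUE
})

#' @param observer,rois,study,referencedImages,frameOfReference,observerType
#'   See slots.
#' @rdname MeasurementReport-class
#' @export
measurementReport <- function(observer, rois, study, referencedImages,
                              frameOfReference,
                              observerType = "person") {
  new("MeasurementReport", observer_name = observer,
      observer_type = observerType, study_uid = study,
      referenced_images = referencedImages, rois = rois,
      frame_of_reference_uid = frameOfReference)
}

setMethod("show", "MeasurementReport", function(object) {
  cat(sprintf("MeasurementReport by %s (%s): %d ROI(s)\n",
              object@observer_name, object@observer_type,
              length(object@rois)))
})

# ---- drawing: pixels -> slide space ----------------------------------

.expected_point_count <- function(graphicType, n) {
  switch(graphicType,
         POINT = n == 1, POLYLINE = n >= 2, POLYGON = n >= 3,
         ELLIPSE = n == 4, ELLIPSOID = n == 6,
         dcmStop("geometry", "unknown graphic type %s", graphicType))
}

#' Build an ROI graphic from image-space points
#'
#' Transforms sub-pixel (column, row) points of the base-level total
#' pixel matrix into 3D slide coordinates through the slide's affine
#' map. Because the stored coordinates live in the frame of reference
#' rather than any pixel matrix, the resulting ROI is valid for every
#' resolution level and channel of the slide. Open polygons are
#' auto-closed with a notice.
#'
#' @param graphicType One of POINT, POLYLINE, POLYGON, ELLIPSE,
#'   ELLIPSOID.
#' @param pixelPoints Numeric matrix n x 2 of (column, row).
#' @param map The slide's base-level [AffineMap-class].
#' @param frameOfReference Frame of reference UID.
#' @return A [RoiGraphic-class].
#' @export
roiFromPixels <- function(graphicType, pixelPoints, map, frameOfReference) {
  p <- .as_points(pixelPoints, 2L)
  if (!.expected_point_count(graphicType, nrow(p)))
    dcmStop("geometry", "invalid point count (%d) for %s", nrow(p),
            graphicType)
  if (graphicType == "POLYGON" && !all(p[1, ] == p[nrow(p), ])) {
    dcmNotice("closing open polygon (first point appended)")
    p <- rbind(p, p[1, ])
  }
  if (graphicType == "POLYGON" && nrow(p) < 4)
    dcmStop("geometry", "polygon needs at least 3 distinct vertices")
  roiGraphic(graphicType, pixelToSlide(map, p), frameOfReference)
}

# ---- measurements -----------------------------------------------------

.shoelace_area <- function(xy) {
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

.path_length <- function(xy, closed = FALSE) {
  if (closed && !all(xy[1, ] == xy[nrow(xy), ])) xy <- rbind(xy, xy[1, ])
  d <- diff(xy)
  sum(sqrt(rowSums(d^2)))
}

#' Compute standard size measurements of a planar ROI
#'
#' POLYGON: shoelace area (mm^2) and perimeter (mm). ELLIPSE: area
#' `pi * a * b` and circumference by Ramanujan's approximation.
#' POLYLINE: path length. POINT: no measurements. The graphic must be
#' planar (all z equal within 1e-3 mm).
#'
#' @param graphic A [RoiGraphic-class].
#' @return List of [Measurement-class] with UCUM units.
#' @examples
#' # a 1 mm x 1 mm square has area 1 mm^2 and perimeter 4 mm
#' @export
measureRoi <- function(graphic) {
  z <- graphic@points[, 3]
  if (diff(range(z)) > 1e-3)
    dcmStop("planarity", "graphic points are not coplanar (z spread %.3g mm)",
            diff(range(z)))
  xy <- graphic@points[, 1:2, drop = FALSE]
  switch(graphic@graphic_type,
    POINT = list(),
    POLYLINE = list(
      measurement(.code_length(), .path_length(xy), .ucum_mm())),
    POLYGON = list(
      measurement(.code_area(), .shoelace_area(xy[-nrow(xy), , drop = FALSE]),
                  .ucum_mm2()),
      measurement(.code_perimeter(), .path_length(xy), .ucum_mm())),
    ELLIPSE = {
      a <- sqrt(sum((xy[2, ] - xy[1, ])^2)) / 2
      b <- sqrt(sum((xy[4, ] - xy[3, ])^2)) / 2
      h <- ((a - b) / (a + b))^2
      circ <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
      list(measurement(.code_area(), pi * a * b, .ucum_mm2()),
           measurement(.code_circumference(), circ, .ucum_mm()))
    },
    ELLIPSOID = dcmStop("planarity",
                        "ELLIPSOID is not a planar graphic; no 2D measures"))
}

# ---- SR encoding ------------------------------------------------------

.sr_code <- c(report = "126000", imaging_measurements = "126010",
              measurement_group = "125007", tracking_id = "112039",
              tracking_uid = "112040", image_region = "111030",
              finding = "121071", person_observer = "121008",
              device_observer = "121012")

.sr_code_item <- function(key, meaning) {
  dicomDataset(CodeValue = .sr_code[[key]], CodingSchemeDesignator = "DCM",
               CodeMeaning = meaning)
}

.content_item <- function(relationship, valueType, nameItem, ...) {
  ds <- dicomDataset(RelationshipType = relationship, ValueType = valueType,
                     ...)
  if (!is.null(nameItem))
    ds <- dcmSet(ds, "ConceptNameCodeSequence", list(nameItem))
  ds
}

.encode_roi_group <- function(roi) {
  children <- list(
    .content_item("HAS OBS CONTEXT", "TEXT",
                  .sr_code_item("tracking_id", "Tracking Identifier"),
                  TextValue = roi@tracking_identifier),
    .content_item("HAS OBS CONTEXT", "UIDREF",
                  .sr_code_item("tracking_uid", "Tracking Unique Identifier"),
                  UID = roi@tracking_uid),
    {
      g <- roi@graphic
      .content_item("CONTAINS", "SCOORD3D",
                    .sr_code_item("image_region", "Image Region"),
                    GraphicType = g@graphic_type,
                    GraphicData = as.numeric(t(g@points)),
                    ReferencedFrameOfReferenceUID = g@frame_of_reference_uid)
    })
  if (!is.null(roi@finding)) {
    item <- .content_item("CONTAINS", "CODE",
                          .sr_code_item("finding", "Finding"))
    item <- dcmSet(item, "ConceptCodeSequence", list(codeItem(roi@finding)))
    children[[length(children) + 1L]] <- item
  }
  for (ev in roi@evaluations) {
    item <- .content_item("CONTAINS", "CODE", codeItem(ev@name))
    item <- dcmSet(item, "ConceptCodeSequence", list(codeItem(ev@value)))
    children[[length(children) + 1L]] <- item
  }
  for (m in roi@measurements) {
    mv <- dicomDataset(NumericValue = m@value,
                       MeasurementUnitsCodeSequence = list(codeItem(m@unit)))
    item <- .content_item("CONTAINS", "NUM", codeItem(m@name),
                          MeasuredValueSequence = list(mv))
    children[[length(children) + 1L]] <- item
  }
  grp <- .content_item("CONTAINS", "CONTAINER",
                       .sr_code_item("measurement_group", "Measurement Group"),
                       ContinuityOfContent = "SEPARATE")
  dcmSet(grp, "ContentSequence", children)
}

#' Encode a measurement report as a Comprehensive 3D SR dataset
#'
#' One planar-ROI measurement group per ROI, each carrying tracking
#' identifier and UID, the SCOORD3D image region with its frame of
#' reference, coded evaluations, and numeric measurements with UCUM
#' units. The observer identity is recorded in observation context.
#'
#' @param report A [MeasurementReport-class].
#' @param uids UID generator.
#' @return A `DicomDataset`.
#' @export
encodeMeasurementReport <- function(report, uids = uidFactory()) {
  fors <- vapply(report@rois, function(r) r@graphic@frame_of_reference_uid, "")
  if (length(unique(c(fors, report@frame_of_reference_uid))) > 1)
    dcmStop("reference", "mixed frames of reference in report")
  observer <- if (report@observer_type == "person") {
    .content_item("HAS OBS CONTEXT", "PNAME",
                  .sr_code_item("person_observer", "Person Observer Name"),
                  PersonName = report@observer_name)
  } else {
    .content_item("HAS OBS CONTEXT", "UIDREF",
                  .sr_code_item("device_observer", "Device Observer UID"),
                  UID = report@observer_name)
  }
  groups <- lapply(report@rois, .encode_roi_group)
  measurements <- .content_item(
    "CONTAINS", "CONTAINER",
    .sr_code_item("imaging_measurements", "Imaging Measurements"),
    ContinuityOfContent = "SEPARATE")
  measurements <- dcmSet(measurements, "ContentSequence", groups)
  evidence <- list(dicomDataset(
    StudyInstanceUID = report@study_uid,
    ReferencedSeriesSequence = lapply(report@referenced_images, function(ref)
      dicomDataset(
        SeriesInstanceUID = ref$series,
        ReferencedSOPSequence = list(dicomDataset(
          ReferencedSOPClassUID = ref$sop_class %||% SOP_VL_WSI,
          ReferencedSOPInstanceUID = ref$instance))))))
  root <- dicomDataset(
    SOPClassUID = SOP_COMPREHENSIVE_3D_SR,
    SOPInstanceUID = uids(),
    StudyInstanceUID = report@study_uid,
    SeriesInstanceUID = uids(),
    Modality = "SR",
    InstanceNumber = 1L,
    CompletionFlag = "COMPLETE",
    VerificationFlag = "UNVERIFIED",
    ValueType = "CONTAINER",
    ContinuityOfContent = "SEPARATE",
    ConceptNameCodeSequence = list(
      .sr_code_item("report", "Imaging Measurement Report")),
    ContentTemplateSequence = list(dicomDataset(
      MappingResource = "DCMR", TemplateIdentifier = "1500")),
    CurrentRequestedProcedureEvidenceSequence = evidence
  )
  dcmSet(root, "ContentSequence", c(list(observer), list(measurements)))
}

.find_items <- function(items, code) {
  Filter(function(it) {
    nm <- dcmValue(it, "ConceptNameCodeSequence", list())
    length(nm) >= 1 &&
      identical(dcmValue(nm[[1L]], "CodeValue", ""), code) &&
      identical(dcmValue(nm[[1L]], "CodingSchemeDesignator", ""), "DCM")
  }, items)
}

.decode_roi_group <- function(grp, index) {
  items <- dcmValue(grp, "ContentSequence", list())
  sc <- Filter(function(it)
    identical(dcmValue(it, "ValueType", ""), "SCOORD3D"), items)
  if (!length(sc))
    dcmStop("group_parse", "measurement group %d has no SCOORD3D item", index)
  sc <- sc[[1L]]
  pts <- matrix(dcmValue(sc, "GraphicData"), ncol = 3L, byrow = TRUE)
  graphic <- roiGraphic(dcmValue(sc, "GraphicType"), pts,
                        dcmValue(sc, "ReferencedFrameOfReferenceUID", ""))
  tid <- .find_items(items, .sr_code[["tracking_id"]])
  tuid <- .find_items(items, .sr_code[["tracking_uid"]])
  finding_items <- .find_items(items, .sr_code[["finding"]])
  finding <- if (length(finding_items)) {
    cs <- dcmValue(finding_items[[1L]], "ConceptCodeSequence", list())
    if (length(cs)) codeFromItem(cs[[1L]]) else NULL
  } else NULL
  evaluations <- list(); measurements <- list(); extras <- list()
  for (it in items) {
    vt <- dcmValue(it, "ValueType", "")
    nm_seq <- dcmValue(it, "ConceptNameCodeSequence", list())
    nm <- if (length(nm_seq)) codeFromItem(nm_seq[[1L]]) else NULL
    if (vt == "CODE" && !is.null(nm) &&
        !(nm@scheme == "DCM" && nm@value == .sr_code[["finding"]])) {
      cs <- dcmValue(it, "ConceptCodeSequence", list())
      if (length(cs))
        evaluations[[length(evaluations) + 1L]] <-
          evaluation(nm, codeFromItem(cs[[1L]]))
    } else if (vt == "NUM" && !is.null(nm)) {
      mv <- dcmValue(it, "MeasuredValueSequence", list())
      if (length(mv)) {
        unit_seq <- dcmValue(mv[[1L]], "MeasurementUnitsCodeSequence", list())
        measurements[[length(measurements) + 1L]] <- measurement(
          nm, dcmValue(mv[[1L]], "NumericValue"),
          if (length(unit_seq)) codeFromItem(unit_seq[[1L]])
          else CodedConcept("1", "UCUM", "no units"))
      }
    } else if (!vt %in% c("SCOORD3D", "TEXT", "UIDREF", "CODE", "NUM")) {
      extras[[length(extras) + 1L]] <- it   # template is extensible
    }
  }
  roi <- roiAnnotation(
    trackingId = if (length(tid)) dcmValue(tid[[1L]], "TextValue", "") else "",
    trackingUid = if (length(tuid)) dcmValue(tuid[[1L]], "UID", "") else "",
    graphic = graphic, finding = finding,
    evaluations = evaluations, measurements = measurements)
  attr(roi, "extras") <- extras
  roi
}

#' Decode a Comprehensive 3D SR dataset into a measurement report
#'
#' Inverse of [encodeMeasurementReport()]. Unknown extra content
#' items are preserved as opaque extras (the template is extensible),
#' not errors; a group missing its SCOORD3D item is reported as a
#' group-level warning while the remaining groups are still returned.
#'
#' @param ds A `DicomDataset`.
#' @return A [MeasurementReport-class].
#' @export
decodeMeasurementReport <- function(ds) {
  if (!identical(dcmValue(ds, "SOPClassUID", ""), SOP_COMPREHENSIVE_3D_SR))
    dcmStop("wrong_sop_class", "dataset is not a Comprehensive 3D SR")
  items <- dcmValue(ds, "ContentSequence", list())
  obs_p <- .find_items(items, .sr_code[["person_observer"]])
  obs_d <- .find_items(items, .sr_code[["device_observer"]])
  observer <- if (length(obs_p))
    list(name = dcmValue(obs_p[[1L]], "PersonName", ""), type = "person")
  else if (length(obs_d))
    list(name = dcmValue(obs_d[[1L]], "UID", ""), type = "device")
  else list(name = "", type = "person")
  container <- .find_items(items, .sr_code[["imaging_measurements"]])
  groups <- if (length(container))
    dcmValue(container[[1L]], "ContentSequence", list()) else list()
  rois <- list()
  for (i in seq_along(groups)) {
    roi <- tryCatch(.decode_roi_group(groups[[i]], i), error = function(e) {
      dcmWarn("group_parse", "skipping measurement group %d: %s", i,
              conditionMessage(e))
      NULL
    })
    if (!is.null(roi)) rois[[length(rois) + 1L]] <- roi
  }
  refs <- list()
  for (ev in dcmValue(ds, "CurrentRequestedProcedureEvidenceSequence",
                      list())) {
    for (se in dcmValue(ev, "ReferencedSeriesSequence", list())) {
      for (so in dcmValue(se, "ReferencedSOPSequence", list())) {
        refs[[length(refs) + 1L]] <- list(
          study = dcmValue(ev, "StudyInstanceUID", ""),
          series = dcmValue(se, "SeriesInstanceUID", ""),
          instance = dcmValue(so, "ReferencedSOPInstanceUID", ""),
          sop_class = dcmValue(so, "ReferencedSOPClassUID", ""))
      }
    }
  }
  frame_of_ref <- if (length(rois))
    rois[[1L]]@graphic@frame_of_reference_uid else ""
  measurementReport(observer = observer$name, observerType = observer$type,
                    rois = rois, study = dcmValue(ds, "StudyInstanceUID", ""),
                    referencedImages = refs,
                    frameOfReference = frame_of_ref)
}
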