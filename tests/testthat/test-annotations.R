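# ROI graphics, measurements, SR round trips, bulk annotations,
# contour conversion and GeoJSON interoperability.

idMap <- function(spacing = 0.001)
  buildPixelToSlide(identityMetadata(spacing = spacing))

test_that("pixel-space drawing transforms to slide space with auto-closing", {
  map <- idMap()
  p <- roiFromPixels("POINT", c(0, 0), map, "1.5")
  expect_equal(p@points[1, ], c(x = 0, y = 0, z = 0))
  expect_message(
    sq <- roiFromPixels("POLYGON",
                        cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)),
                        map, "1.5"),
    "closing open polygon")
  expect_identical(nrow(sq@points), 5L)
  expect_equal(sq@points[1, ], sq@points[5, ])
  expect_equal(max(sq@points[, 1]), 1)   # 1 mm square
  expect_error(roiFromPixels("ELLIPSE", cbind(1:3, 1:3), map, "1.5"),
               class = "dicomslide_geometry")
})

test_that("planar measurements match closed forms", {
  map <- idMap()
  sq <- suppressMessages(roiFromPixels(
    "POLYGON", cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)), map, "1.5"))
  m <- measureRoi(sq)
  vals <- setNames(vapply(m, function(x) x@value, 0),
                   vapply(m, function(x) x@name@meaning, ""))
  expect_equal(unname(vals["Area"]), 1)
  expect_equal(unname(vals["Perimeter"]), 4)
  expect_identical(m[[1L]]@unit@value, "mm2")
  expect_identical(m[[1L]]@unit@scheme, "UCUM")
  tri <- roiGraphic("POLYGON",
                    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 0)),
                    "1.5")
  expect_equal(measureRoi(tri)[[1L]]@value, 0.5)
  # circle drawn as an ELLIPSE with both axes 2 mm long
  circ <- roiGraphic("ELLIPSE",
                     rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0)),
                     "1.5")
  mc <- measureRoi(circ)
  expect_equal(mc[[1L]]@value, pi, tolerance = 1e-9)
  expect_equal(mc[[2L]]@value, 2 * pi, tolerance = 1e-4)  # Ramanujan
  expect_identical(measureRoi(roiGraphic("POINT", cbind(1, 2, 0), "1.5")),
                   list())
  tilted <- roiGraphic("POLYLINE", rbind(c(0, 0, 0), c(1, 0, 0.5)), "1.5")
  expect_error(measureRoi(tilted), class = "dicomslide_planarity")
})

test_that("polygon area agrees with a Monte-Carlo estimate within 3 SE", {
  set.seed(77)
  theta <- sort(runif(8, 0, 2 * pi))
  r <- runif(8, 0.5, 1.5)
  verts <- cbind(r * cos(theta), r * sin(theta))
  poly <- roiGraphic("POLYGON", cbind(rbind(verts, verts[1, ]), 0), "1.5")
  area <- measureRoi(poly)[[1L]]@value
  n <- 1e5
  pts <- cbind(runif(n, -1.5, 1.5), runif(n, -1.5, 1.5))
  inside <- vapply(seq_len(n), function(i)
    oraclePointInPolygon(pts[i, 1], pts[i, 2], verts), TRUE)
  phat <- mean(inside)
  mc <- phat * 9
  se <- 9 * sqrt(phat * (1 - phat) / n)
  expect_lt(abs(mc - area), 3 * se)
})

test_that("measurement reports survive the SR encode/decode round trip", {
  map <- idMap()
  uids <- uidFactory(60)
  g <- suppressMessages(roiFromPixels(
    "POLYGON", cbind(c(10, 50, 50, 10), c(10, 10, 50, 50)), map, "1.5"))
  roi <- roiAnnotation(
    "ROI-1", uids(), g,
    finding = CodedConcept("108369006", "SCT", "Tumor"),
    evaluations = list(evaluation(
      CodedConcept("Q-001", "99DSL", "Malignancy"),
      CodedConcept("A-002", "99DSL", "Malignant"))),
    measurements = measureRoi(g))
  report <- measurementReport(
    observer = "Reader^One", rois = list(roi), study = "1.2",
    referencedImages = list(list(study = "1.2", series = "1.3",
                                 instance = "1.4",
                                 sop_class = "1.2.840.10008.5.1.4.1.1.77.1.6")),
    frameOfReference = "1.5")
  ds <- encodeMeasurementReport(report, uids)
  path <- withr::local_tempfile(fileext = ".dcm")
  writeDicomFile(ds, path)
  back <- decodeMeasurementReport(readDicomFile(path)$dataset)
  expect_identical(back@observer_name, "Reader^One")
  expect_length(back@rois, 1L)
  r2 <- back@rois[[1L]]
  expect_identical(r2@tracking_identifier, "ROI-1")
  expect_identical(r2@tracking_uid, roi@tracking_uid)
  expect_lt(max(abs(r2@graphic@points - g@points)), 1e-6)
  expect_true(codedEqual(r2@finding, roi@finding))
  expect_true(codedEqual(r2@evaluations[[1L]]@name,
                         roi@evaluations[[1L]]@name))
  expect_true(codedEqual(r2@evaluations[[1L]]@value,
                         roi@evaluations[[1L]]@value))
  expect_equal(vapply(r2@measurements, function(m) m@value, 0),
               vapply(roi@measurements, function(m) m@value, 0))
  expect_identical(back@referenced_images[[1L]]$instance, "1.4")
})

test_that("a 100-ROI report encodes 100 groups with distinct tracking UIDs", {
  map <- idMap()
  uids <- uidFactory(61)
  rois <- lapply(1:100, function(i) {
    g <- roiGraphic("POINT", cbind(i, i, 0), "1.5")
    roiAnnotation(sprintf("ROI-%d", i), uids(), g)
  })
  report <- measurementReport("Reader^Two", rois, "1.2",
                              list(list(study = "1.2", series = "1.3",
                                        instance = "1.4",
                                        sop_class = "x")), "1.5")
  ds <- encodeMeasurementReport(report, uids)
  container <- dcmValue(ds, "ContentSequence")[[2L]]
  expect_length(dcmValue(container, "ContentSequence"), 100L)
  back <- decodeMeasurementReport(ds)
  tuids <- vapply(back@rois, function(r) r@tracking_uid, "")
  expect_length(unique(tuids), 100L)
})

test_that("groups missing SCOORD3D are skipped with a warning, others kept", {
  map <- idMap(); uids <- uidFactory(62)
  rois <- lapply(1:3, function(i)
    roiAnnotation(sprintf("R%d", i), uids(),
                  roiGraphic("POINT", cbind(i, 0, 0), "1.5")))
  ds <- encodeMeasurementReport(
    measurementReport("R", rois, "1.2", list(), "1.5"), uids)
  cs <- dcmValue(ds, "ContentSequence")
  groups <- dcmValue(cs[[2L]], "ContentSequence")
  # strip the SCOORD3D item from group 2
  items <- dcmValue(groups[[2L]], "ContentSequence")
  items <- Filter(function(it) dcmValue(it, "ValueType", "") != "SCOORD3D",
                  items)
  groups[[2L]] <- dcmSet(groups[[2L]], "ContentSequence", items)
  cs[[2L]] <- dcmSet(cs[[2L]], "ContentSequence", groups)
  ds <- dcmSet(ds, "ContentSequence", cs)
  expect_warning(back <- decodeMeasurementReport(ds),
                 class = "dicomslide_group_parse")
  expect_length(back@rois, 2L)
})

test_that("bulk annotations round-trip large point sets and measurements", {
  bf <- smallBrightfield(seed = 63, baseSize = 128, tileSize = 64,
                         levels = 1)
  src <- bf$instances[[1L]]$dataset
  set.seed(63)
  centroids <- lapply(seq_len(10000), function(i)
    matrix(runif(2, 0, 127), 1, 2))
  areas <- runif(10000, 10, 80)
  group <- list(label = CodedConcept("84640000", "SCT", "Nucleus"),
                graphic_type = "POINT", polygons = centroids,
                measurements = list(list(
                  name = CodedConcept("42798000", "SCT", "Area"),
                  unit = CodedConcept("um2", "UCUM", "square micrometer"),
                  values = areas)))
  ds <- buildBulkAnnotations(list(group), src, uidFactory(63))
  path <- withr::local_tempfile(fileext = ".dcm")
  writeDicomFile(ds, path)
  groups <- parseBulkAnnotations(
    readDicomFile(path)$dataset,
    map = buildPixelToSlide(parseImageMetadata(src)))
  expect_length(groups, 1L)
  g <- groups[[1L]]
  expect_identical(g$count, 10000L)
  expect_length(g$points_px, 10000L)
  expect_length(g$measurements[[1L]]$values, 10000L)
  expect_equal(g$measurements[[1L]]$values, areas, tolerance = 1e-6)
  expect_equal(g$points_px[[17L]][1, ], centroids[[17L]][1, ],
               tolerance = 1e-5)
  expect_length(g$points_mm, 10000L)
  expect_identical(ncol(g$points_mm[[1L]]), 3L)
})

test_that("inconsistent bulk coordinate data raises group errors", {
  bf <- smallBrightfield(seed = 64, baseSize = 64, tileSize = 64, levels = 1)
  src <- bf$instances[[1L]]$dataset
  polys <- list(cbind(c(1, 10, 10), c(1, 1, 10)),
                cbind(c(20, 30, 30), c(20, 20, 30)))
  ds <- buildBulkAnnotations(list(list(
    label = CodedConcept("84640000", "SCT", "Nucleus"),
    graphic_type = "POLYGON", polygons = polys)), src, uidFactory(64))
  # truncate the coordinate data: second polygon extends past the end
  grp <- dcmValue(ds, "AnnotationGroupSequence")[[1L]]
  pcd <- dcmValue(grp, "PointCoordinatesData")
  grp <- dcmSet(grp, "PointCoordinatesData", pcd[1:(length(pcd) - 16)])
  ds <- dcmSet(ds, "AnnotationGroupSequence", list(grp))
  expect_error(parseBulkAnnotations(ds), class = "dicomslide_group")
})

test_that("rasterization agrees with the point-in-polygon oracle", {
  set.seed(65)
  for (trial in 1:4) {
    k <- sample(3:7, 1)
    theta <- sort(runif(k, 0, 2 * pi))
    r <- runif(k, 5, 28)
    poly <- cbind(32 + r * cos(theta), 32 + r * sin(theta))
    mask <- rasterizePolygons(list(poly), 64, 64)
    for (px in seq(0, 63, by = 3)) {
      for (py in seq(0, 63, by = 3)) {
        expect_identical(mask[py + 1, px + 1],
                         oraclePointInPolygon(px, py, poly),
                         info = sprintf("trial %d (%d,%d)", trial, px, py))
      }
    }
  }
})

test_that("contour tables convert to bulk + segmentation with exact fills", {
  bf <- smallBrightfield(seed = 66, baseSize = 64, tileSize = 64, levels = 1)
  src <- bf$instances[[1L]]$dataset
  df <- data.frame(
    object_id = c(1, 2),
    vertices = c("10 10;19 10;19 19;10 19", "30 30;39 30;39 39;30 39"),
    area_px = c(100, 100))
  res <- convertContourTable(df, src, uidFactory(66))
  expect_length(res$errors, 0L)
  seg_px <- DicomSlide:::.datasetRegionArray(res$segmentation)
  expect_identical(sum(seg_px), 200)   # two disjoint 10x10 squares
  groups <- parseBulkAnnotations(res$bulk)
  expect_identical(groups[[1L]]$count, 2L)
  # single square fill count, as its own conversion
  res1 <- convertContourTable(data.frame(
    object_id = 1, vertices = "10 10;19 10;19 19;10 19"), src,
    uidFactory(67))
  expect_identical(sum(DicomSlide:::.datasetRegionArray(res1$segmentation)),
                   100)
  # malformed rows are reported per row; empty tables are errors
  bad <- data.frame(object_id = c(1, 2),
                    vertices = c("10 10;19 10;19 19;10 19", "not vertices"))
  res2 <- convertContourTable(bad, src, uidFactory(68))
  expect_length(res2$errors, 1L)
  expect_match(res2$errors, "row 2")
  expect_error(convertContourTable(data.frame(), src),
               class = "dicomslide_empty_input")
})

test_that("GeoJSON export/import round-trips geometry to 1e-6 mm", {
  map <- idMap()
  sq <- suppressMessages(roiFromPixels(
    "POLYGON", cbind(c(10, 500, 500, 10), c(10, 10, 500, 500)), map, "1.5"))
  pt <- roiFromPixels("POINT", c(12.5, 80.25), map, "1.5")
  json <- roisToGeoJson(list(sq, pt), map)
  back <- suppressMessages(roisFromGeoJson(json, map, "1.5"))
  expect_length(back, 2L)
  expect_lt(max(abs(back[[1L]]@points - sq@points)), 1e-6)
  expect_lt(max(abs(back[[2L]]@points - pt@points)), 1e-6)
})

test_that("stored SCOORD3D coordinates are independent of the drawing level", {
  slide <- sharedBrightfieldSlide()
  lv <- volumeLevels(slide)
  map_base <- buildPixelToSlide(lv[[1L]]@metadata)
  map_low <- buildPixelToSlide(lv[[2L]]@metadata)
  base_px <- cbind(c(40, 200, 200, 40), c(40, 40, 200, 200))
  low_px <- base_px / lv[[2L]]@downsample_col
  a <- suppressMessages(roiFromPixels("POLYGON", base_px, map_base,
                                      slide@frame_of_reference_uid))
  b <- suppressMessages(roiFromPixels("POLYGON", low_px, map_low,
                                      slide@frame_of_reference_uid))
  expect_lt(max(abs(a@points - b@points)),
            lv[[1L]]@metadata@pixel_spacing_col_mm / 2)
})

test_that("configured code sets reject unlisted answer codes", {
  codes <- defaultAnnotationCodeSet()
  good <- evaluation(CodedConcept("Q-001", "99DSL", "Malignancy"),
                     CodedConcept("A-001", "99DSL", "Benign"))
  expect_true(validateEvaluation(codes, good))
  bad <- evaluation(CodedConcept("Q-001", "99DSL", "Malignancy"),
                    CodedConcept("FREE-TEXT", "99DSL", "whatever"))
  expect_error(validateEvaluation(codes, bad),
               class = "dicomslide_code_set")
})
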