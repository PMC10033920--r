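# Metadata parsing and coded concepts.

test_that("coded concepts compare on value and scheme only", {
  a <- CodedConcept("14885008", "SCT", "Vimentin")
  b <- CodedConcept("14885008", "SCT", "vimentin protein")
  c <- CodedConcept("14885008", "DCM", "Vimentin")
  expect_true(codedEqual(a, b))
  expect_false(codedEqual(a, c))
  expect_error(CodedConcept("", "SCT"), "non-empty")
})

test_that("a 512x512 matrix with 256x256 tiles parses to 4 TILED_FULL frames", {
  bf <- makeBrightfieldSeries(fixtureSpec(seed = 5, baseSize = 512,
                                          tileSize = 256, levels = 1))
  md <- parseImageMetadata(bf$instances[[1L]]$dataset)
  expect_s4_class(md, "SlideImageMetadata")
  expect_identical(numFrames(md), 4L)
  expect_identical(md@dimension_organization, "TILED_FULL")
  expect_identical(imageFlavor(md), "VOLUME")
  expect_identical(c(totalPixelMatrixRows(md), totalPixelMatrixCols(md)),
                   c(512, 512))
})

test_that("DICOM JSON parse equals Part-10 parse field-by-field", {
  bf <- sharedFixtures()$brightfield
  for (x in bf$instances[1:2]) {
    ds <- dcmSet(x$dataset, "TransferSyntaxUID", x$transferSyntax)
    from_part10 <- parseImageMetadata(ds)
    json <- datasetsToJson(list(ds))
    from_json <- parseImageMetadata(datasetsFromJson(json)[[1L]])
    for (sl in slotNames("SlideImageMetadata")) {
      if (sl == "palette_lut") next
      expect_equal(slot(from_json, sl), slot(from_part10, sl),
                   info = sl, tolerance = 1e-9)
    }
  }
})

test_that("missing required attributes and wrong SOP classes are rejected by name", {
  bf <- makeBrightfieldSeries(fixtureSpec(seed = 6, baseSize = 128,
                                          tileSize = 64, levels = 1))
  ds <- bf$instances[[1L]]$dataset
  broken <- ds
  broken[["SharedFunctionalGroupsSequence"]] <- NULL
  err <- expect_error(parseImageMetadata(broken),
                      class = "dicomslide_missing_attribute")
  expect_match(conditionMessage(err), "PixelSpacing")
  wrong <- dcmSet(ds, "SOPClassUID", "1.2.840.10008.5.1.4.1.1.2")
  expect_error(parseImageMetadata(wrong),
               class = "dicomslide_wrong_sop_class")
})

test_that("metadata round-trips through write/read for every generator fixture", {
  fx <- sharedFixtures()
  store <- sharedFixtureStore()
  for (x in c(fx$brightfield$instances[1:2], fx$fluorescence$instances[1:2])) {
    md0 <- parseImageMetadata(dcmSet(x$dataset, "TransferSyntaxUID",
                                     x$transferSyntax))
    reread <- retrieveMetadata(store, md0@study_uid, md0@series_uid,
                               md0@sop_instance_uid)
    md1 <- parseImageMetadata(reread)
    for (sl in slotNames("SlideImageMetadata")) {
      if (sl == "palette_lut") next
      expect_equal(slot(md1, sl), slot(md0, sl), info = sl,
                   tolerance = 1e-9)
    }
  }
})

test_that("specimen staining parses coded targets in document order", {
  fl <- makeFluorescenceSeries(fixtureSpec(
    seed = 7, kind = "fluorescence", baseSize = 64, tileSize = 64,
    levels = 1, channels = c("DNA", "CD45")))
  targets <- parseSpecimenStaining(fl$instances[[1L]]$dataset)
  expect_length(targets, 1L)  # one series per channel, one target each
  expect_true(codedEqual(targets[[1L]],
                         DicomSlide:::.stainingConcept("DNA")))
  # brightfield fixtures carry the two H&E substances in order
  bf <- makeBrightfieldSeries(fixtureSpec(seed = 7, baseSize = 64,
                                          tileSize = 64, levels = 1))
  he <- parseSpecimenStaining(bf$instances[[1L]]$dataset)
  expect_length(he, 2L)
  expect_identical(vapply(he, function(x) x@value, ""),
                   c("12710003", "255801000"))
  # absence of specimen metadata yields an empty list
  bare <- dicomDataset(SOPInstanceUID = "1")
  expect_identical(parseSpecimenStaining(bare), list())
})

test_that("the nine-target multiplexed panel parses to nine coded concepts", {
  panel <- stainingTargetCodes()$name
  expect_length(panel, 9L)
  fl <- makeFluorescenceSeries(fixtureSpec(
    seed = 8, kind = "fluorescence", baseSize = 64, tileSize = 64,
    levels = 1, channels = panel))
  targets <- lapply(fl$instances, function(x)
    parseSpecimenStaining(x$dataset)[[1L]])
  expect_length(targets, 9L)
  expect_identical(vapply(targets, function(x) x@meaning, ""),
                   stainingTargetCodes()$meaning)
})
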