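# Local store, DICOMweb client, and their observational equivalence.

webTwin <- function(store) {
  dicomWebStore("http://fixture.local/dicomweb",
                transport = dicomwebHandler(store))
}

test_that("study search counts fixture studies and respects filters and paging", {
  store <- sharedFixtureStore()
  studies <- searchObjects(store, searchFilter("study"))
  expect_length(studies, 2L)   # brightfield + fluorescence
  # instance-level search constrained to slide-microscopy images
  wsi <- searchObjects(store, searchFilter(
    "instance", list(SOPClassUID = "1.2.840.10008.5.1.4.1.1.77.1.6")))
  all_inst <- searchObjects(store, searchFilter("instance"))
  expect_gt(length(all_inst), length(wsi))
  expect_true(all(vapply(wsi, function(x)
    x$SOPClassUID == "1.2.840.10008.5.1.4.1.1.77.1.6", TRUE)))
  # paging: offset/limit slices the deterministic ordering
  page1 <- searchObjects(store, searchFilter("instance", limit = 3))
  page2 <- searchObjects(store, searchFilter("instance", offset = 3,
                                             limit = 3))
  expect_length(page1, 3L)
  expect_identical(all_inst[4:6], page2)
  expect_error(searchFilter("instance", list(PatientWeight = "70")),
               class = "dicomslide_unsupported_filter")
})

test_that("local and DICOMweb backends are observationally equivalent", {
  store <- sharedFixtureStore()
  web <- webTwin(store)
  for (level in c("study", "series", "instance")) {
    a <- searchObjects(store, searchFilter(level))
    b <- searchObjects(web, searchFilter(level))
    expect_identical(a, b, info = level)
  }
  inst <- searchObjects(store, searchFilter(
    "instance", list(SOPClassUID = "1.2.840.10008.5.1.4.1.1.77.1.6")))[[1L]]
  md_local <- retrieveMetadata(store, inst$StudyInstanceUID,
                               inst$SeriesInstanceUID, inst$SOPInstanceUID)
  md_web <- retrieveMetadata(web, inst$StudyInstanceUID,
                             inst$SeriesInstanceUID, inst$SOPInstanceUID)
  expect_true(dicomEqual(md_local, md_web))
  req <- frameRequest(inst$StudyInstanceUID, inst$SeriesInstanceUID,
                      inst$SOPInstanceUID, c(1, 2))
  fr_local <- retrieveFrames(store, req)
  fr_web <- retrieveFrames(web, req)
  expect_identical(fr_local, fr_web)   # byte-identical uncompressed frames
})

test_that("frame retrieval is pure, sized correctly, and range-checked", {
  store <- sharedFixtureStore()
  inst <- searchObjects(store, searchFilter(
    "instance", list(SOPClassUID = "1.2.840.10008.5.1.4.1.1.77.1.6")))[[1L]]
  md <- parseImageMetadata(retrieveMetadata(
    store, inst$StudyInstanceUID, inst$SeriesInstanceUID,
    inst$SOPInstanceUID))
  req <- frameRequest(inst$StudyInstanceUID, inst$SeriesInstanceUID,
                      inst$SOPInstanceUID, 1)
  fr <- retrieveFrames(store, req)
  expect_length(fr, 1L)
  expect_identical(fr[[1L]]$mediaType, "application/octet-stream")
  expect_length(fr[[1L]]$bytes,
                as.integer(md@tile_rows * md@tile_cols *
                             md@samples_per_pixel * md@bits_allocated / 8))
  expect_identical(retrieveFrames(store, req), fr)   # purity
  bad <- frameRequest(inst$StudyInstanceUID, inst$SeriesInstanceUID,
                      inst$SOPInstanceUID, 99)
  err <- expect_error(retrieveFrames(store, bad),
                      class = "dicomslide_frame_range")
  expect_match(conditionMessage(err), "99")
  expect_error(frameRequest("1", "2", "3", c(2, 1)), "sorted")
})

test_that("JPEG-compressed fixtures negotiate the image/jpeg media type", {
  dir <- withr::local_tempdir()
  store <- localStore(dir)
  bf <- makeBrightfieldSeries(fixtureSpec(seed = 11, baseSize = 128,
                                          tileSize = 64, levels = 1,
                                          compression = "jpeg"))
  storeInstances(store, bf$instances)
  md <- parseImageMetadata(dcmSet(bf$instances[[1L]]$dataset,
                                  "TransferSyntaxUID",
                                  bf$instances[[1L]]$transferSyntax))
  req <- frameRequest(md@study_uid, md@series_uid, md@sop_instance_uid, 1,
                      mediaTypes = c("image/jpeg"))
  fr <- retrieveFrames(store, req)[[1L]]
  expect_identical(fr$mediaType, "image/jpeg")
  # decoded JPEG approximates the ground truth (lossy codec)
  tile <- decodeFrame(fr$bytes, fr$mediaType, md)
  expect_lt(mean(abs(tile - bf$ground_truth[[1L]][1:64, 1:64, ])), 4)
  # transcoding path: only octet-stream accepted
  req2 <- frameRequest(md@study_uid, md@series_uid, md@sop_instance_uid, 1,
                       mediaTypes = "application/octet-stream")
  fr2 <- retrieveFrames(store, req2)[[1L]]
  expect_identical(fr2$mediaType, "application/octet-stream")
  expect_error(retrieveFrames(store, frameRequest(
    md@study_uid, md@series_uid, md@sop_instance_uid, 1,
    mediaTypes = "image/jls")), class = "dicomslide_negotiation")
})

test_that("stored instances become searchable; duplicates are reported per instance", {
  dir <- withr::local_tempdir()
  store <- localStore(dir)
  uids <- uidFactory(42)
  bf <- makeBrightfieldSeries(fixtureSpec(seed = 12, baseSize = 64,
                                          tileSize = 64, levels = 1))
  storeInstances(store, bf$instances[1])
  src <- bf$instances[[1L]]$dataset
  analysis <- makeAnalysisObjects(src, list(cbind(c(5, 20, 20, 5),
                                                  c(5, 5, 20, 20))),
                                  uids = uids)
  r1 <- storeInstances(store, list(analysis$sr))
  expect_identical(r1$status, "stored")
  hits <- searchObjects(store, searchFilter(
    "instance", list(SOPClassUID = "1.2.840.10008.5.1.4.1.1.88.34")))
  expect_length(hits, 1L)
  # storing the same SR again reports a duplicate, others unaffected
  r2 <- storeInstances(store, list(analysis$sr, analysis$bulk))
  expect_identical(r2$status, c("duplicate", "stored"))
})

test_that("multi-store configuration routes annotations to their own store", {
  img_dir <- withr::local_tempdir(); ann_dir <- withr::local_tempdir()
  images <- localStore(img_dir); anns <- localStore(ann_dir)
  cfg <- storeConfig(list(images, anns),
                     roles = list("images",
                                  c("annotations-read", "annotations-write")))
  bf <- makeBrightfieldSeries(fixtureSpec(seed = 13, baseSize = 64,
                                          tileSize = 64, levels = 1))
  storeInstances(storeForRole(cfg, "images"), bf$instances[1])
  analysis <- makeAnalysisObjects(bf$instances[[1L]]$dataset,
                                  list(cbind(c(5, 20, 20, 5),
                                             c(5, 5, 20, 20))))
  before <- searchObjects(images, searchFilter("instance"))
  storeInstances(storeForRole(cfg, "annotations-write"), list(analysis$sr))
  after <- searchObjects(images, searchFilter("instance"))
  expect_identical(before, after)   # image store untouched
  expect_length(searchObjects(anns, searchFilter("instance")), 1L)
})

test_that("STOW through the DICOMweb client round-trips instances", {
  dir <- withr::local_tempdir()
  store <- localStore(dir)
  web <- webTwin(store)
  bf <- makeBrightfieldSeries(fixtureSpec(seed = 14, baseSize = 64,
                                          tileSize = 64, levels = 1))
  receipt <- storeInstances(web, bf$instances[1])
  expect_identical(receipt$status, "stored")
  hits <- searchObjects(web, searchFilter("instance"))
  expect_length(hits, 1L)
  md <- retrieveMetadata(web, hits[[1L]]$StudyInstanceUID,
                         hits[[1L]]$SeriesInstanceUID,
                         hits[[1L]]$SOPInstanceUID)
  expect_s4_class(parseImageMetadata(md), "SlideImageMetadata")
  expect_error(retrieveMetadata(web, "0.0", "0.0", "0.0"),
               class = "dicomslide_transport")
})

test_that("transport failures surface as structured transport errors", {
  failing <- function(method, url, headers, body)
    list(status = 503L, headers = character(0), body = raw(0))
  web <- dicomWebStore("http://down.example", transport = failing)
  err <- expect_error(searchObjects(web, searchFilter("study")),
                      class = "dicomslide_transport")
  expect_match(conditionMessage(err), "503")
  # bearer tokens from the provider are injected into request headers
  seen <- NULL
  capture <- function(method, url, headers, body) {
    seen <<- headers
    list(status = 200L, headers = c(`Content-Type` = "application/dicom+json"),
         body = charToRaw("[]"))
  }
  web2 <- dicomWebStore("http://auth.example", transport = capture,
                        tokenProvider = function() "secret-token")
  searchObjects(web2, searchFilter("study"))
  expect_identical(unname(seen[["Authorization"]]), "Bearer secret-token")
})
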