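# Advanced Blending Presentation States.

test_that("blending states round-trip through the DICOM encoding exactly", {
  fl <- sharedFixtures()$fluorescence
  slide <- sharedFluorescenceSlide()
  md <- volumeLevels(slide, "DNA")[[1L]]@metadata
  green <- list(list(kind = "discrete", length = 1, value = 0),
                list(kind = "linear", length = 255, value = 255))
  black <- list(list(kind = "discrete", length = 256, value = 0))
  state <- blendingState(
    "DNA only",
    list(blendingChannel(md@study_uid, md@series_uid, md@sop_instance_uid,
                         voiWindow(32768, 65536),
                         paletteColorLut(black, green, black,
                                         source = "presentation_state"),
                         opticalPath = "DNA")),
    md@study_uid)
  ds <- buildPresentationState(state, slide, uids = uidFactory(50))
  # serialize to Part-10 and back: binary segment descriptors survive
  path <- withr::local_tempfile(fileext = ".dcm")
  writeDicomFile(ds, path)
  back <- parsePresentationState(readDicomFile(path)$dataset)
  expect_true(blendingStateEqual(state, back))
  expect_equal(back@channels[[1L]]@window@center, 32768)
  expect_equal(back@channels[[1L]]@window@width, 65536)
})

test_that("dangling image references are rejected", {
  slide <- sharedFluorescenceSlide()
  md <- volumeLevels(slide, "DNA")[[1L]]@metadata
  state <- blendingState(
    "bad", list(blendingChannel(md@study_uid, md@series_uid,
                                "1.2.3.999", voiWindow(100, 200),
                                colorRampLut(c(255, 0, 0)))),
    md@study_uid)
  expect_error(buildPresentationState(state, slide),
               class = "dicomslide_reference")
})

test_that("the nine-target slide yields three default states of sizes 4, 3, 3", {
  slide <- sharedFluorescenceSlide()
  states <- defaultStainingGroups(slide)
  expect_length(states, 3L)
  expect_identical(vapply(states, function(s) length(s@channels), 0L),
                   c(4L, 3L, 3L))
  dss <- lapply(states, buildPresentationState, slide = slide,
                uids = uidFactory(51))
  parsed <- lapply(dss, parsePresentationState)
  expect_identical(vapply(parsed, function(s) length(s@channels), 0L),
                   c(4L, 3L, 3L))
})

test_that("partial panels form partial groups; uncoded slides form none", {
  fl2 <- makeFluorescenceSeries(fixtureSpec(
    seed = 52, kind = "fluorescence", baseSize = 64, tileSize = 64,
    levels = 1, channels = c("DNA", "CD45")))
  states <- defaultStainingGroups(slideOf(fl2$instances))
  # DNA and CD45 match group 1; CD45 alone matches group 3
  expect_length(states, 2L)
  expect_identical(length(states[[1L]]@channels), 2L)
  # a slide with no coded targets yields no states
  bf <- sharedFixtures()$brightfield
  expect_length(defaultStainingGroups(sharedBrightfieldSlide()), 0L)
})

test_that("state rendering equals the per-channel scalar chain and is pure", {
  store <- sharedFixtureStore()
  fl <- sharedFixtures()$fluorescence
  slide <- sharedFluorescenceSlide()
  md <- volumeLevels(slide, "DNA")[[1L]]@metadata
  red <- colorRampLut(c(255, 0, 0), source = "presentation_state")
  state <- blendingState(
    "red DNA",
    list(blendingChannel(md@study_uid, md@series_uid, md@sop_instance_uid,
                         voiWindow(32768, 65536), red,
                         opticalPath = "DNA")),
    md@study_uid)
  region <- c(0, 0, 64, 64)
  out <- renderWithState(store, slide, 1, region, state)
  truth <- fl$ground_truth$DNA[[1L]][1:64, 1:64]
  oracle <- applyPalette(applyVoi(truth, voiWindow(32768, 65536)), red)
  expect_identical(out, oracle)
  # purity: rendering twice yields identical arrays
  expect_identical(renderWithState(store, slide, 1, region, state), out)
  # stored pixels are untouched by rendering
  before <- readRegion(store, slide, 1, region, channel = "DNA")$pixels
  renderWithState(store, slide, 1, region, state)
  after <- readRegion(store, slide, 1, region, channel = "DNA")$pixels
  expect_identical(before, after)
})

test_that("disjoint channel blobs take their own channel's color under blending", {
  store <- sharedFixtureStore()
  fl <- sharedFixtures()$fluorescence
  slide <- sharedFluorescenceSlide()
  states <- defaultStainingGroups(slide)
  region <- c(0, 0, 256, 256)
  out <- renderWithState(store, slide, 1, region, states[[2L]])
  # group 2 = CD3 (blue ramp), CD68 (green), CD20 (red)
  chans <- states[[2L]]@channels
  for (i in seq_along(chans)) {
    nm <- chans[[i]]@optical_path
    mask <- fl$masks[[nm]]
    core <- mask & fl$ground_truth[[nm]][[1L]] > 50000  # blob centers
    expect_gt(sum(core), 0)
    top <- expandPalette(chans[[i]]@lut)
    # at blob cores the dominant channel color matches the assigned hue
    hue <- c(top$red[256], top$green[256], top$blue[256])
    dominant <- which.max(hue)
    vals <- apply(out, 3, function(m) mean(m[core]))
    expect_identical(which.max(vals), dominant)
  }
})
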